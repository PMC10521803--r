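# Low-level vector / polygon helpers shared by all modules. Everything is in
# millimetres; points are rows of n x 3 (or n x 2) numeric matrices.

cross3 <- function(a, b) {
  c(a[2] * b[3] - a[3] * b[2],
    a[3] * b[1] - a[1] * b[3],
    a[1] * b[2] - a[2] * b[1])
}

vnorm <- function(v) sqrt(sum(v^2))

unit3 <- function(v, what = "vector") {
  n <- vnorm(v)
  if (n < 1e-12) stop("cannot normalise a zero-length ", what, call. = FALSE)
  v / n
}

#' Signed area of a closed 2D polygon
#'
#' Positive for counterclockwise vertex order (shoelace formula). The polygon
#' is implicitly closed: the last vertex connects back to the first.
#'
#' @param p n x 2 matrix of vertices.
#' @return Signed area.
#' @keywords internal
polygon_signed_area <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

#' Area centroid of a closed 2D polygon
#' @param p n x 2 matrix of vertices.
#' @return Length-2 centroid.
#' @keywords internal
polygon_centroid <- function(p) {
  x <- p[, 1]; y <- p[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(p))  # degenerate: fall back to vertex mean
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

polygon_perimeter <- function(p) {
  pn <- rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
  sum(sqrt(rowSums((pn - p)^2)))
}

#' Ellipse perimeter (Ramanujan's second approximation)
#'
#' Accurate to better than 1e-9 relative for the mild eccentricities of
#' cranial outlines; used by the synthetic reference-table generator. Tests
#' check it against adaptive quadrature independently.
#'
#' @param a,b Semi-axes (mm).
#' @return Perimeter (mm).
#' @keywords internal
ellipse_perimeter <- function(a, b) {
  h <- ((a - b) / (a + b))^2
  pi * (a + b) * (1 + 3 * h / (10 + sqrt(4 - 3 * h)))
}
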