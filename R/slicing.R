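# Mesh-plane sectioning: closed contour extraction, the iterative search for
# the maximum-OFD axial slice, orthogonal sagittal/coronal slices, and the
# 120-point angular resampling that gives pointwise correspondence across
# subjects.

#' Construct a cutting plane
#'
#' @param origin Point on the plane (mm).
#' @param normal Plane normal (normalised internally).
#' @param orientation_label One of `"axial"`, `"sagittal"`, `"coronal"` or
#'   `NA` for a free plane.
#' @return An object of class `cutting_plane`.
#' @export
cutting_plane <- function(origin, normal, orientation_label = NA_character_) {
  if (!is.na(orientation_label))
    orientation_label <- match.arg(orientation_label, c("axial", "sagittal", "coronal"))
  structure(list(origin = as.numeric(origin),
                 normal = unit3(as.numeric(normal), "plane normal"),
                 orientation_label = orientation_label),
            class = "cutting_plane")
}

# Right-handed in-plane basis (u, v) with cross(u, v) = +normal. For the
# canonical orientations the basis is fixed so signed areas/orientations are
# reproducible; otherwise an arbitrary orthonormal pair is constructed.
plane_basis <- function(plane) {
  n <- plane$normal
  lbl <- plane$orientation_label
  if (!is.na(lbl)) {
    basis <- switch(lbl,
      axial    = list(u = c(1, 0, 0), v = c(0, 1, 0)),
      sagittal = list(u = c(0, 1, 0), v = c(0, 0, 1)),
      coronal  = list(u = c(0, 0, 1), v = c(1, 0, 0)))
    if (vnorm(cross3(basis$u, basis$v) - n) < 1e-9) return(basis)
  }
  a <- if (abs(n[1]) < 0.9) c(1, 0, 0) else c(0, 1, 0)
  u <- unit3(cross3(a, n))
  list(u = u, v = cross3(n, u))
}

#' Construct a planar contour
#'
#' An ordered closed polyline of 3D points lying in a cutting plane. Points
#' are ordered counterclockwise when viewed from the +normal side; the last
#' point connects implicitly back to the first.
#'
#' @param points k x 3 matrix of points in the plane (k >= 8 for measurement
#'   contours).
#' @param plane The [cutting_plane()] the points lie in.
#' @param closed Logical; measurement contours are closed.
#' @return An object of class `planar_contour`.
#' @export
planar_contour <- function(points, plane, closed = TRUE) {
  points <- as.matrix(points)
  d <- abs(as.numeric(points %*% plane$normal) - sum(plane$origin * plane$normal))
  if (max(d) > 1e-6)
    stop("contour points deviate from plane by ", signif(max(d), 3), " mm",
         call. = FALSE)
  structure(list(points = points, plane = plane, closed = closed),
            class = "planar_contour")
}

#' @export
print.planar_contour <- function(x, ...) {
  cat(sprintf("<planar_contour> %d points, %s, %s, perimeter %.1f mm\n",
              nrow(x$points), x$plane$orientation_label,
              if (x$closed) "closed" else "open", contour_perimeter(x)))
  invisible(x)
}

#' Perimeter of a contour (closing segment included when closed)
#' @param contour A [planar_contour()].
#' @return Length in mm.
#' @export
contour_perimeter <- function(contour) {
  p <- contour$points
  q <- if (contour$closed) rbind(p[-1, , drop = FALSE], p[1, , drop = FALSE])
       else p[-1, , drop = FALSE]
  if (!contour$closed) p <- p[-nrow(p), , drop = FALSE]
  sum(sqrt(rowSums((q - p)^2)))
}

# In-plane 2D coordinates of a contour w.r.t. the plane's right-handed basis.
contour_points_2d <- function(contour) {
  b <- plane_basis(contour$plane)
  rel <- sweep(contour$points, 2, contour$plane$origin)
  cbind(as.numeric(rel %*% b$u), as.numeric(rel %*% b$v))
}

# Area centroid of the contour, returned in the plane's (u, v) coordinates
# relative to the plane origin.
contour_centroid_2d <- function(contour) {
  polygon_centroid(contour_points_2d(contour))
}

# Centroid in world coordinates.
contour_centroid_3d <- function(contour) {
  b <- plane_basis(contour$plane)
  c2 <- contour_centroid_2d(contour)
  contour$plane$origin + c2[1] * b$u + c2[2] * b$v
}

#' Intersect a triangle mesh with a plane
#'
#' Sections every crossing triangle, chains the resulting segments into
#' closed loops via shared mesh edges, and returns the loop with the largest
#' perimeter (small spurious loops — ears or nose clipped by the plane — are
#' discarded). Contour points are ordered counterclockwise when viewed from
#' the +normal side. Vertices lying exactly on the plane are handled by
#' nudging the plane 1e-7 mm along its normal, well inside the 1e-6 mm
#' planarity tolerance.
#'
#' @param mesh A [cranio_mesh()].
#' @param plane A [cutting_plane()].
#' @return A closed [planar_contour()].
#' @export
intersect_plane <- function(mesh, plane) {
  stopifnot(inherits(mesh, "cranio_mesh"), inherits(plane, "cutting_plane"))
  v <- mesh$vertices; f <- mesh$faces
  d <- as.numeric(v %*% plane$normal) - sum(plane$origin * plane$normal)
  if (any(abs(d) < 1e-9)) d <- d + 1e-7  # nudge plane off exact vertices
  df <- matrix(d[f], ncol = 3L)
  crossing <- which(matrixStats_rowMins(df) < 0 & matrixStats_rowMaxs(df) > 0)
  if (!length(crossing))
    stop("empty-section error: plane does not intersect the mesh", call. = FALSE)

  # for each crossing face, the two edges whose endpoints straddle the plane
  edge_pairs <- rbind(c(1L, 2L), c(2L, 3L), c(3L, 1L))
  seg_from <- character(length(crossing)); seg_to <- character(length(crossing))
  pts_env <- new.env(parent = emptyenv())
  for (si in seq_along(crossing)) {
    fi <- crossing[si]
    tri <- f[fi, ]
    keys <- character(0)
    for (e in 1:3) {
      a <- tri[edge_pairs[e, 1]]; b <- tri[edge_pairs[e, 2]]
      if (d[a] * d[b] < 0) {
        key <- paste0(min(a, b), "_", max(a, b))
        if (is.null(pts_env[[key]])) {
          t <- d[a] / (d[a] - d[b])
          pts_env[[key]] <- v[a, ] + t * (v[b, ] - v[a, ])
        }
        keys <- c(keys, key)
      }
    }
    if (length(keys) != 2L)
      stop("degenerate plane-triangle intersection", call. = FALSE)
    seg_from[si] <- keys[1]; seg_to[si] <- keys[2]
  }

  nodes <- unique(c(seg_from, seg_to))
  ia <- match(seg_from, nodes); ib <- match(seg_to, nodes)
  # adjacency: each node of a watertight section belongs to exactly 2 segments
  deg <- tabulate(c(ia, ib), length(nodes))
  if (any(deg != 2L))
    stop("open-contour error: section crosses a non-watertight region",
         call. = FALSE)
  nbr <- matrix(0L, length(nodes), 2)
  slot <- integer(length(nodes))
  for (si in seq_along(ia)) {
    slot[ia[si]] <- slot[ia[si]] + 1L; nbr[ia[si], slot[ia[si]]] <- ib[si]
    slot[ib[si]] <- slot[ib[si]] + 1L; nbr[ib[si], slot[ib[si]]] <- ia[si]
  }

  visited <- logical(length(nodes))
  loops <- list()
  for (start in seq_along(nodes)) {
    if (visited[start]) next
    loop <- integer(0); prev <- 0L; cur <- start
    repeat {
      visited[cur] <- TRUE
      loop <- c(loop, cur)
      nxt <- if (nbr[cur, 1] != prev) nbr[cur, 1] else nbr[cur, 2]
      prev <- cur; cur <- nxt
      if (cur == start) break
    }
    loops[[length(loops) + 1L]] <- loop
  }

  loop_points <- lapply(loops, function(lp)
    do.call(rbind, lapply(nodes[lp], function(k) pts_env[[k]])))
  perims <- vapply(loop_points, polygon_perimeter, numeric(1))
  pts <- loop_points[[which.max(perims)]]

  # orient counterclockwise as seen from +normal
  b <- plane_basis(plane)
  rel <- sweep(pts, 2, plane$origin)
  p2 <- cbind(as.numeric(rel %*% b$u), as.numeric(rel %*% b$v))
  if (polygon_signed_area(p2) < 0) pts <- pts[rev(seq_len(nrow(pts))), , drop = FALSE]
  planar_contour(pts, plane, closed = TRUE)
}

# rowMins/rowMaxs for a 3-column matrix without extra dependencies
matrixStats_rowMins <- function(m) pmin(m[, 1], m[, 2], m[, 3])
matrixStats_rowMaxs <- function(m) pmax(m[, 1], m[, 2], m[, 3])

#' Find the axial slice with the largest occipitofrontal diameter
#'
#' Iterates axial planes z = z_min, z_min + step, ... <= z_max over the
#' cranial side of a registered mesh and returns the contour maximising the
#' OFD (anteroposterior extent); ties break toward the inferior (smaller z)
#' slice. The search trace is attached as attribute `"trace"` (a data.frame
#' of z and ofd).
#'
#' @param mesh A registered [cranio_mesh()] (nasion-tragi plane at z = 0).
#' @param step Slice step in mm (default 1).
#' @param z_min,z_max Search bounds in mm; defaults 0 and the mesh maximum z.
#' @return The maximising closed axial [planar_contour()].
#' @export
find_max_ofd_slice <- function(mesh, step = 1, z_min = 0, z_max = NULL) {
  stopifnot(inherits(mesh, "cranio_mesh"), step > 0)
  if (is.null(z_max)) z_max <- max(mesh$vertices[, 3]) - 1e-6
  zs <- seq(z_min, z_max, by = step)
  best <- NULL
  trace_z <- numeric(0); trace_ofd <- numeric(0)
  for (z in zs) {
    contour <- tryCatch(
      intersect_plane(mesh, cutting_plane(c(0, 0, z), c(0, 0, 1), "axial")),
      error = function(e) NULL)
    if (is.null(contour)) next
    ofd <- measure_ofd(contour)
    trace_z <- c(trace_z, z); trace_ofd <- c(trace_ofd, ofd)
    if (is.null(best) || ofd > best$ofd + 1e-12) best <- list(ofd = ofd, contour = contour)
  }
  if (is.null(best))
    stop("orientation error: no axial plane intersects the registered mesh",
         call. = FALSE)
  attr(best$contour, "trace") <- data.frame(z = trace_z, ofd = trace_ofd)
  best$contour
}

#' Extract the sagittal and coronal contours orthogonal to the axial slice
#'
#' The sagittal plane passes through the axial contour centroid's x with
#' normal +x; the coronal plane through the centroid's y with normal +y.
#'
#' @param mesh A registered [cranio_mesh()].
#' @param axial The axial [planar_contour()] from [find_max_ofd_slice()].
#' @return A list with elements `sagittal` and `coronal`.
#' @export
extract_orthogonal_contours <- function(mesh, axial) {
  stopifnot(inherits(axial, "planar_contour"))
  ctr <- contour_centroid_3d(axial)
  list(
    sagittal = intersect_plane(mesh, cutting_plane(c(ctr[1], 0, 0), c(1, 0, 0),
                                                   "sagittal")),
    coronal  = intersect_plane(mesh, cutting_plane(c(0, ctr[2], 0), c(0, 1, 0),
                                                   "coronal")))
}

# Contour-local 2D frames for resampling: axial (x, y), sagittal (y, z),
# coronal (x, z). Angle 0 is the local ordinate (+y anterior for axial,
# +z superior for sagittal and coronal), proceeding counterclockwise.
contour_local_2d <- function(contour) {
  lbl <- contour$plane$orientation_label
  if (is.na(lbl)) stop("contour has no orientation label", call. = FALSE)
  cols <- switch(lbl, axial = c(1, 2), sagittal = c(2, 3), coronal = c(1, 3))
  contour$points[, cols, drop = FALSE]
}

#' Resample a closed contour at equally spaced angles
#'
#' Converts the contour to its local 2D frame and samples the radial distance
#' from the area centroid at `n_samples` equally spaced angles, starting at
#' the local ordinate axis (anterior for axial slices, superior for sagittal
#' and coronal) and proceeding counterclockwise. Sample k corresponds to
#' angle 2*pi*k/n_samples, which guarantees pointwise index correspondence
#' across subjects. The contour must be star-shaped about its centroid.
#'
#' @param contour A closed [planar_contour()] with an orientation label.
#' @param n_samples Number of samples (default 120).
#' @return An object of class `sampled_contour` with fields `points`
#'   (n x 2 local coordinates), `radii`, `center`, `start_direction`,
#'   `n_samples`, `orientation_label`.
#' @export
resample_contour <- function(contour, n_samples = 120) {
  stopifnot(inherits(contour, "planar_contour"), n_samples >= 4)
  if (!contour$closed) stop("contour must be closed for resampling", call. = FALSE)
  p <- contour_local_2d(contour)
  ctr <- polygon_centroid(p)
  a <- sweep(p, 2, ctr)
  b <- rbind(a[-1, , drop = FALSE], a[1, , drop = FALSE])
  angles <- pi / 2 + 2 * pi * (seq_len(n_samples) - 1) / n_samples
  radii <- numeric(n_samples)
  for (k in seq_len(n_samples)) {
    w <- c(cos(angles[k]), sin(angles[k]))
    # solve t*w = a + s*(b - a) for each segment; star-shaped => exactly 1 hit
    e <- b - a
    denom <- w[1] * e[, 2] - w[2] * e[, 1]
    s <- (w[2] * a[, 1] - w[1] * a[, 2]) / denom
    t <- if (abs(w[1]) > abs(w[2])) (a[, 1] + s * e[, 1]) / w[1]
         else (a[, 2] + s * e[, 2]) / w[2]
    hit <- which(abs(denom) > 1e-12 & s >= -1e-9 & s <= 1 + 1e-9 & t > 1e-9)
    tv <- sort(t[hit])
    # a vertex sitting exactly on the ray is hit through both adjacent
    # segments: collapse crossings closer than 1e-6 mm before counting
    if (length(tv) > 1L) tv <- tv[c(TRUE, diff(tv) > 1e-6)]
    if (length(tv) != 1L)
      stop(sprintf(
        "sampling error: contour is not star-shaped about its centroid (%d crossings at angle %.1f deg)",
        length(tv), (angles[k] - pi / 2) * 180 / pi), call. = FALSE)
    radii[k] <- tv[1]
  }
  pts <- cbind(ctr[1] + radii * cos(angles), ctr[2] + radii * sin(angles))
  structure(list(points = pts, radii = radii, center = ctr,
                 start_direction = c(0, 1), n_samples = as.integer(n_samples),
                 orientation_label = contour$plane$orientation_label),
            class = "sampled_contour")
}

#' @export
print.sampled_contour <- function(x, ...) {
  cat(sprintf("<sampled_contour> %s, %d samples, mean radius %.1f mm\n",
              x$orientation_label, x$n_samples, mean(x$radii)))
  invisible(x)
}

#' Write a contour to CSV
#'
#' Columns: `angle_deg`, `radius_mm`, `x_mm`, `y_mm` (local frame) for a
#' sampled contour; `x_mm,y_mm,z_mm` for a raw planar contour.
#'
#' @param contour A `sampled_contour` or [planar_contour()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_contour_csv <- function(contour, path) {
  if (inherits(contour, "sampled_contour")) {
    df <- data.frame(
      angle_deg = 360 * (seq_len(contour$n_samples) - 1) / contour$n_samples,
      radius_mm = contour$radii,
      x_mm = contour$points[, 1], y_mm = contour$points[, 2])
  } else if (inherits(contour, "planar_contour")) {
    df <- data.frame(x_mm = contour$points[, 1], y_mm = contour$points[, 2],
                     z_mm = contour$points[, 3])
  } else stop("unsupported contour object", call. = FALSE)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
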