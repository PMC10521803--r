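# Shared fixtures. Everything is generated in code; expensive meshes are
# built once per test run and memoised here.

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(key, builder) {
  if (is.null(.fixture_cache[[key]])) .fixture_cache[[key]] <- builder()
  .fixture_cache[[key]]
}

# canonical 200 x 150 x 90 ellipsoid head, noiseless, subdivision 4
ellipsoid_head <- function() {
  cached("ellipsoid", function()
    generate_head(head_spec(length_mm = 200, width_mm = 150, height_mm = 90,
                            noise_sd_mm = 0, mesh_resolution = 4, seed = 1)))
}

# smaller/faster variant for I/O and validation tests
small_head <- function() {
  cached("small", function()
    generate_head(head_spec(length_mm = 200, width_mm = 150, height_mm = 90,
                            noise_sd_mm = 0, mesh_resolution = 2, seed = 1)))
}

registered_ellipsoid <- function() {
  cached("registered_ellipsoid", function() {
    h <- ellipsoid_head()
    suppressMessages(register_head(h$mesh, h$landmarks))
  })
}

# closed polygonal circle contour in the axial plane
circle_contour <- function(r = 80, n = 720, label = "axial") {
  th <- 2 * pi * (seq_len(n) - 1) / n
  p2 <- cbind(r * cos(th), r * sin(th))
  pts <- switch(label,
    axial = cbind(p2, 0),
    sagittal = cbind(0, p2),
    coronal = cbind(p2[, 1], 0, p2[, 2]))
  normal <- switch(label, axial = c(0, 0, 1), sagittal = c(1, 0, 0),
                   coronal = c(0, 1, 0))
  planar_contour(pts, cutting_plane(c(0, 0, 0), normal, label))
}

# closed axial ellipse contour (semi-axis a along x, b along y)
ellipse_contour <- function(a, b, n = 720) {
  th <- 2 * pi * (seq_len(n) - 1) / n
  planar_contour(cbind(a * cos(th), b * sin(th), 0),
                 cutting_plane(c(0, 0, 0), c(0, 0, 1), "axial"))
}

# independent quadrature oracle for the ellipse perimeter
ellipse_perimeter_quadrature <- function(a, b) {
  4 * stats::integrate(function(t) sqrt((a * sin(t))^2 + (b * cos(t))^2),
                       0, pi / 2, rel.tol = 1e-10)$value
}

canonical_landmarks <- function() {
  cranio_landmarks(nasion = c(0, 100, 0), tragus_left = c(-70, 0, 0),
                   tragus_right = c(70, 0, 0))
}

landmark_coords <- function(lm) {
  rbind(lm$nasion, lm$tragus_left, lm$tragus_right)
}
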