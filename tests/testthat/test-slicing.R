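# mesh-plane sectioning, max-OFD slice search, 120-point resampling

test_that("unit icosphere equator contour has perimeter ~ 2*pi", {
  ico <- craniometrics:::icosphere(4)
  ct <- intersect_plane(ico, cutting_plane(c(0, 0, 0), c(0, 0, 1), "axial"))
  expect_lt(abs(contour_perimeter(ct) - 2 * pi) / (2 * pi), 0.01)
})

test_that("ellipsoid sections match the quadrature perimeter oracle", {
  h <- ellipsoid_head()  # semi-axes x 75, y 100, z 90
  ct <- intersect_plane(h$mesh, cutting_plane(c(0, 0, 0), c(0, 0, 1), "axial"))
  oracle <- ellipse_perimeter_quadrature(75, 100)
  expect_lt(abs(contour_perimeter(ct) - oracle) / oracle, 0.005)
})

test_that("planes missing the mesh raise an empty-section error", {
  h <- small_head()
  zmax <- max(h$mesh$vertices[, 3])
  expect_error(intersect_plane(h$mesh,
                               cutting_plane(c(0, 0, 2 * zmax), c(0, 0, 1), "axial")),
               "empty-section")
})

test_that("open meshes raise an open-contour error", {
  ico <- craniometrics:::icosphere(3)
  sphere <- cranio_mesh(ico$vertices * 100, ico$faces)
  # delete the faces around the +x equator vertex: the equatorial slice now
  # crosses a hole and only open chains remain there
  side <- which.max(sphere$vertices[, 1])
  holed <- cranio_mesh(sphere$vertices,
                       sphere$faces[rowSums(sphere$faces == side) == 0, ])
  expect_error(intersect_plane(holed,
                               cutting_plane(c(0, 0, 0), c(0, 0, 1), "axial")),
               "open-contour")
})

test_that("contours are counterclockwise and rigid-motion invariant in perimeter", {
  h <- ellipsoid_head()
  ct <- intersect_plane(h$mesh, cutting_plane(c(0, 0, 10), c(0, 0, 1), "axial"))
  expect_gt(craniometrics:::polygon_signed_area(
    craniometrics:::contour_points_2d(ct)), 0)
  m <- random_rigid_transform(13)
  moved <- apply_transform(h$mesh, m)
  n2 <- as.numeric(m$rotation %*% c(0, 0, 1))
  o2 <- as.numeric(m$rotation %*% c(0, 0, 10)) + m$translation
  ct2 <- intersect_plane(moved, cutting_plane(o2, n2))
  expect_lt(abs(contour_perimeter(ct2) - contour_perimeter(ct)) /
              contour_perimeter(ct), 1e-6)
})

test_that("max-OFD search picks the equator of an ellipsoid and handles coarse steps", {
  reg <- registered_ellipsoid()
  ct <- find_max_ofd_slice(reg$mesh, step = 1)
  expect_lte(ct$plane$origin[3], 1)   # widest section at the reference plane
  tr <- attr(ct, "trace")
  expect_true(is.data.frame(tr) && all(c("z", "ofd") %in% names(tr)))
  expect_gt(nrow(tr), 50)
  # step wider than the head: single candidate slice at z_min
  ct2 <- find_max_ofd_slice(reg$mesh, step = 500)
  expect_equal(ct2$plane$origin[3], 0)
})

test_that("max-OFD search matches a 10x-finer brute force on the bullet head", {
  hb <- generate_head(head_spec(200, 150, 95, occipital_bullet = 12,
                                bullet_width = 0.22, noise_sd_mm = 0,
                                mesh_resolution = 4, seed = 2))
  reg <- suppressMessages(register_head(hb$mesh, hb$landmarks))
  coarse <- find_max_ofd_slice(reg$mesh, step = 1)
  fine <- find_max_ofd_slice(reg$mesh, step = 0.1)
  expect_gt(fine$plane$origin[3], 1)  # optimum genuinely off the plane
  expect_lte(abs(coarse$plane$origin[3] - fine$plane$origin[3]), 1)
})

test_that("orthogonal contours have the right planes and oracle perimeters", {
  reg <- registered_ellipsoid()
  axial <- find_max_ofd_slice(reg$mesh)
  orth <- extract_orthogonal_contours(reg$mesh, axial)
  expect_identical(orth$sagittal$plane$orientation_label, "sagittal")
  expect_identical(orth$coronal$plane$orientation_label, "coronal")
  ctr <- craniometrics:::contour_centroid_3d(axial)
  expect_lt(max(abs(orth$sagittal$points[, 1] - ctr[1])), 1e-6)
  expect_lt(max(abs(orth$coronal$points[, 2] - ctr[2])), 1e-6)
  # sagittal section of the ellipsoid head: semi-axes 100 (y) and 90 (z)
  # above the plane, 0.35*90 below: compare against the piecewise oracle
  upper <- ellipse_perimeter_quadrature(100, 90) / 2
  lower <- ellipse_perimeter_quadrature(100, 0.35 * 90) / 2
  oracle <- upper + lower
  expect_lt(abs(contour_perimeter(orth$sagittal) - oracle) / oracle, 0.005)
})

test_that("sphere sagittal and coronal perimeters agree", {
  hs <- generate_head(head_spec(180, 180, 90, noise_sd_mm = 0,
                                mesh_resolution = 4, seed = 3))
  reg <- suppressMessages(register_head(hs$mesh, hs$landmarks))
  axial <- find_max_ofd_slice(reg$mesh)
  orth <- extract_orthogonal_contours(reg$mesh, axial)
  ps <- contour_perimeter(orth$sagittal); pc <- contour_perimeter(orth$coronal)
  expect_lt(abs(ps - pc) / ps, 0.001)
})

test_that("resampling reproduces circle and ellipse radii at axis angles", {
  rs <- resample_contour(circle_contour(80), 120)
  expect_identical(rs$n_samples, 120L)
  expect_lt(max(abs(rs$radii - 80)), 0.1)
  re <- resample_contour(ellipse_contour(75, 100, n = 2880), 120)
  expect_lt(abs(re$radii[1] - 100), 0.2)    # angle 0 = +y (anterior)
  expect_lt(abs(re$radii[31] - 75), 0.2)    # angle 90 = -x direction
})

test_that("120-gon reconstruction keeps the contour perimeter within 0.5%", {
  reg <- registered_ellipsoid()
  axial <- find_max_ofd_slice(reg$mesh)
  rs <- resample_contour(axial, 120)
  full <- contour_perimeter(axial)
  expect_lt(abs(craniometrics:::polygon_perimeter(rs$points) - full) / full,
            0.005)
})

test_that("in-plane rotation by one angular step permutes sample indices by one", {
  reg <- registered_ellipsoid()
  axial <- find_max_ofd_slice(reg$mesh)
  rs <- resample_contour(axial, 120)
  th <- 2 * pi / 120  # 3 degrees
  rot <- rbind(c(cos(th), -sin(th)), c(sin(th), cos(th)))
  p2 <- axial$points[, 1:2] %*% t(rot)
  rotated <- planar_contour(cbind(p2, axial$points[, 3]), axial$plane)
  rs2 <- resample_contour(rotated, 120)
  # CCW rotation by one step: new sample k sees what old sample k-1 saw
  expect_lt(max(abs(rs2$radii - rs$radii[c(120, 1:119)])), 0.05)
})

test_that("non-star-shaped contours are rejected with the offending angle", {
  # horseshoe: outer arc with a gap, closed back along an inner arc; rays
  # from the centroid through the opening cross the wall more than once
  outer_th <- seq(-0.78 * pi, 0.78 * pi, length.out = 80)
  inner_th <- rev(outer_th)
  pts <- rbind(cbind(80 * cos(outer_th), 80 * sin(outer_th)),
               cbind(45 * cos(inner_th), 45 * sin(inner_th)))
  horseshoe <- planar_contour(cbind(pts, 0),
                              cutting_plane(c(0, 0, 0), c(0, 0, 1), "axial"))
  expect_error(resample_contour(horseshoe, 120), "star-shaped")
})

test_that("contours serialize to CSV", {
  rs <- resample_contour(circle_contour(80), 120)
  path <- withr::local_tempfile(fileext = ".csv")
  write_contour_csv(rs, path)
  df <- read.csv(path)
  expect_identical(nrow(df), 120L)
  expect_named(df, c("angle_deg", "radius_mm", "x_mm", "y_mm"))
  expect_equal(df$radius_mm[1], rs$radii[1])
})
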