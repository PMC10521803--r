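# measurements, volume, calibration, z-scores, pipeline

test_that("OFD/BPD/OFC on analytic fixtures match closed forms", {
  ell <- ellipse_contour(75, 100)  # x semi-axis 75, y semi-axis 100
  expect_lt(abs(measure_ofd(ell) - 200), 0.2)
  expect_lt(abs(measure_bpd(ell) - 150), 0.2)
  circ <- circle_contour(80)
  expect_lt(abs(measure_ofd(circ) - 160), 0.1)
  expect_lt(abs(measure_bpd(circ) - 160), 0.1)
  oracle <- ellipse_perimeter_quadrature(75, 100)
  expect_lt(abs(measure_ofc(ell) - oracle) / oracle, 0.005)
  # square fixture: perimeter includes the closing segment
  sq <- planar_contour(rbind(c(0, 0, 0), c(100, 0, 0), c(100, 100, 0),
                             c(50, 100, 0), c(25, 100, 0), c(12, 100, 0),
                             c(5, 100, 0), c(0, 100, 0)),
                       cutting_plane(c(0, 0, 0), c(0, 0, 1), "axial"))
  expect_equal(measure_ofc(sq), 400)
  # homogeneity: doubling coordinates doubles OFC
  ell2 <- ellipse_contour(150, 200)
  expect_equal(measure_ofc(ell2) / measure_ofc(ell), 2, tolerance = 1e-9)
})

test_that("measurements require closed contours", {
  open <- circle_contour(80)
  open$closed <- FALSE
  expect_error(measure_ofd(open), "closed")
  expect_error(measure_ofc(open), "closed")
})

test_that("cephalic index is the bpd/ofd percentage and scale-invariant", {
  expect_equal(cephalic_index(75, 100), 75)
  expect_equal(cephalic_index(100, 100), 100)
  expect_equal(cephalic_index(150, 200), 75)
  expect_error(cephalic_index(75, 0), "positive")
})

test_that("estimate_icv matches half-ellipsoid and hemisphere closed forms", {
  h <- ellipsoid_head()
  icv <- estimate_icv(h$mesh)
  closed_form <- (2 / 3) * pi * 75 * 100 * 90 / 1000
  expect_lt(abs(as.numeric(icv) - closed_form) / closed_form, 0.01)
  # slope 0.5 halves the corrected volume
  half <- estimate_icv(h$mesh, icv_correction(slope = 0.5))
  expect_equal(as.numeric(half), as.numeric(icv) / 2, tolerance = 1e-9)
  expect_equal(attr(half, "raw_cc"), attr(icv, "raw_cc"))
  # sphere of radius 100 capped at the equator: hemisphere 2094.4 cc
  ico <- craniometrics:::icosphere(4)
  sphere <- cranio_mesh(ico$vertices * 100, ico$faces)
  hemi <- estimate_icv(sphere)
  expect_lt(abs(as.numeric(hemi) - 2094.4) / 2094.4, 0.01)
})

test_that("estimate_icv rejects non-watertight meshes", {
  h <- small_head()
  holed <- cranio_mesh(h$mesh$vertices, h$mesh$faces[-1, , drop = FALSE])
  expect_error(estimate_icv(holed), "watertight")
})

test_that("volume calibration recovers planted slopes and validates inputs", {
  raw <- seq(800, 1600, length.out = 10)
  exact <- suppressWarnings(calibrate_icv_correction(raw, 0.9 * raw))
  expect_equal(exact$slope, 0.9, tolerance = 1e-9)
  expect_equal(exact$r_squared, 1, tolerance = 1e-9)
  set.seed(3)
  raw <- runif(25, 800, 1600)
  ct <- 0.88 * raw - 25 + rnorm(25, 0, 20)
  fit <- calibrate_icv_correction(raw, ct)
  expect_lt(abs(fit$slope - 0.88), 0.05)
  expect_identical(fit$n_pairs, 25L)
  # r_squared must match an independent correlation computation
  expect_equal(fit$r_squared, cor(raw, ct)^2, tolerance = 1e-12)
  expect_error(calibrate_icv_correction(c(1, 2), c(1, 2)), "at least 3")
  expect_error(calibrate_icv_correction(rep(1000, 5), rnorm(5, 1000)),
               "degenerate")
})

test_that("z_score interpolates linearly and clamps out-of-range ages", {
  ref <- growth_reference(
    data.frame(age_months = c(12, 24), mean = c(48, 50), sd = c(2, 2)),
    "ofc", "male", "test")
  expect_equal(z_score(49, 18, "male", ref), 0)       # interpolated mean
  expect_equal(z_score(51, 18, "male", ref), 1)       # mean + sd, hand interp
  expect_equal(z_score(50, 24, "male", ref), 0)
  expect_warning(z0 <- z_score(48, 6, "male", ref), "clamped")
  expect_equal(z0, 0)
  expect_error(z_score(49, 18, "female", ref), "lookup")
  # monotone in value, antitone in reference mean
  expect_gt(z_score(52, 18, "male", ref), z_score(51, 18, "male", ref))
})

test_that("growth references round-trip through the CSV schema", {
  refs <- list(ofc = list(
    male = growth_reference(data.frame(age_months = c(0, 12, 24),
                                       mean = c(350, 460, 480),
                                       sd = c(12, 14, 15)), "ofc", "male"),
    female = growth_reference(data.frame(age_months = c(0, 12, 24),
                                         mean = c(345, 455, 475),
                                         sd = c(12, 14, 15)), "ofc", "female")))
  path <- withr::local_tempfile(fileext = ".csv")
  write_growth_references(refs, path)
  back <- read_growth_references(path)
  expect_equal(back$ofc$male$table, refs$ofc$male$table,
               ignore_attr = "row.names")
  expect_identical(back$ofc$female$sex, "female")
})

test_that("measure_head produces a consistent record on the canonical ellipsoid", {
  h <- ellipsoid_head()
  rec <- suppressMessages(measure_head(h$mesh, h$landmarks))
  expect_s3_class(rec, "cephalo_record")
  expect_lt(abs(rec$cephalic_index - 75), 0.3)
  expect_equal(rec$cephalic_index, 100 * rec$bpd / rec$ofd, tolerance = 1e-9)
  expect_lt(abs(rec$ofd - 200), 0.2)
  expect_lt(abs(rec$bpd - 150), 0.2)
  df <- as.data.frame(rec)
  expect_identical(nrow(df), 1L)
  expect_true(all(c("ofd", "bpd", "ofc", "cephalic_index", "icv") %in% names(df)))
})

test_that("measure_head is invariant to rigid motion of mesh and landmarks", {
  h <- ellipsoid_head()
  base <- suppressMessages(measure_head(h$mesh, h$landmarks, compute_icv = FALSE))
  m <- random_rigid_transform(11)
  moved <- suppressMessages(measure_head(apply_transform(h$mesh, m),
                                         transform_landmarks(h$landmarks, m),
                                         compute_icv = FALSE))
  for (fld in c("ofd", "bpd", "ofc", "cephalic_index"))
    expect_lt(abs(moved[[fld]] - base[[fld]]), 1e-4)
})

test_that("z-scores are ~0 when the cohort value equals the reference mean", {
  ref <- generate_reference_table(ages = c(12, 24, 36), n_mc = 500)
  mid <- stats::approx(ref$table$age_months, ref$table$mean, xout = 20)$y
  expect_lt(abs(z_score(mid, 20, "male", ref)), 0.01)
})

test_that("ofc_icv_proxy_check separates coupled from independent data", {
  # exact affine relation
  ofc <- seq(400, 550, length.out = 20)
  recs <- data.frame(ofc = ofc, icv = 3 * ofc - 250)
  expect_equal(suppressWarnings(ofc_icv_proxy_check(recs)), 1, tolerance = 1e-12)
  # independent null
  set.seed(5)
  null_df <- data.frame(ofc = rnorm(200, 480, 20), icv = rnorm(200, 1100, 90))
  expect_lt(ofc_icv_proxy_check(null_df), 0.05)
  expect_error(ofc_icv_proxy_check(data.frame(ofc = 1, icv = 2)), "at least 3")
})

test_that("growth-linked synthetic cohorts couple OFC and ICV strongly", {
  cohort <- generate_cohort(cohort_spec("norm", 25, age_range_months = c(3, 60),
                                        mesh_resolution = 3, seed = 8))
  gt <- lapply(cohort, function(su) su$ground_truth)
  expect_gt(ofc_icv_proxy_check(gt), 0.8)
})
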