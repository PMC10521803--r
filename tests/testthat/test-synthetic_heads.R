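# synthetic head generator: watertightness, determinism, ground truth,
# cohorts and reference tables

test_that("generated heads are watertight with analytically placed landmarks", {
  h <- small_head()
  rep_ <- validate_mesh(h$mesh)
  expect_true(rep_$watertight)
  expect_identical(rep_$n_components, 1L)
  lm <- h$landmarks
  expect_equal(lm$nasion[3], 0)
  expect_equal(lm$tragus_left[3], 0)
  expect_equal(unname(lm$nasion[1]), 0)
  # perturbed + noisy heads stay watertight
  hp <- generate_head(head_spec(190, 150, 100, noise_sd_mm = 0.3,
                                rigid_perturbation = random_rigid_transform(4),
                                mesh_resolution = 2, seed = 9))
  expect_true(validate_mesh(hp$mesh)$watertight)
})

test_that("generator is seed-deterministic", {
  s <- head_spec(190, 150, 100, noise_sd_mm = 0.5, mesh_resolution = 2, seed = 42)
  h1 <- generate_head(s); h2 <- generate_head(s)
  expect_identical(h1$mesh$vertices, h2$mesh$vertices)
  s2 <- head_spec(190, 150, 100, noise_sd_mm = 0.5, mesh_resolution = 2, seed = 43)
  h3 <- generate_head(s2)
  expect_gt(max(abs(h1$mesh$vertices - h3$mesh$vertices)), 0)
})

test_that("ground truth matches closed forms for the pure ellipsoid", {
  h <- ellipsoid_head()
  gt <- h$ground_truth
  expect_equal(gt$ofd, 200, tolerance = 1e-3)
  expect_equal(gt$bpd, 150, tolerance = 1e-3)
  expect_equal(gt$cephalic_index, 75, tolerance = 1e-3)
  closed_form <- (2 / 3) * pi * 75 * 100 * 90 / 1000
  expect_lt(abs(gt$icv - closed_form) / closed_form, 0.001)
  oracle <- ellipse_perimeter_quadrature(75, 100)
  expect_lt(abs(gt$ofc - oracle) / oracle, 0.001)
})

test_that("pipeline recovers generator ground truth on the ellipsoid head", {
  h <- ellipsoid_head()
  rec <- suppressMessages(measure_head(h$mesh, h$landmarks))
  gt <- h$ground_truth
  expect_lt(abs(rec$cephalic_index - gt$cephalic_index), 0.3)
  expect_lt(abs(rec$ofc - gt$ofc) / gt$ofc, 0.005)
  expect_lt(abs(rec$icv - gt$icv) / gt$icv, 0.01)
})

test_that("scaphocephalic cohort recovers its cephalic-index parameter", {
  cohort <- generate_cohort(cohort_spec("scapho", 20,
                                        age_range_months = c(12, 36),
                                        params = cohort_preset("scaphocephalic"),
                                        seed = 1))
  cis <- vapply(cohort, function(su)
    suppressMessages(measure_head(su$mesh, su$landmarks,
                                  compute_icv = FALSE))$cephalic_index,
    numeric(1))
  expect_lt(abs(mean(cis) - 68), 2)
})

test_that("cohort sex ratio matches its binomial distribution", {
  cohort <- generate_cohort(cohort_spec("norm", 200, sex_ratio_male = 0.84,
                                        mesh_resolution = 1, seed = 1))
  frac <- mean(vapply(cohort, function(su) su$sex == "male", logical(1)))
  expect_lt(abs(frac - 0.84), 1.96 * sqrt(0.84 * 0.16 / 200))
})

test_that("ages and ground-truth sizes grow monotonically in expectation", {
  # "in expectation": switch off the between-subject parameter noise so the
  # growth model itself is exercised (with noise the late, saturating part
  # of the curve is legitimately rank-scrambled)
  p <- cohort_preset("normocephalic")
  p$size_cv <- 0; p$ci_sd <- 0; p$height_cv <- 0; p$noise_sd_mm <- 0
  cohort <- generate_cohort(cohort_spec("norm", 40, age_range_months = c(0, 72),
                                        params = p, mesh_resolution = 1,
                                        seed = 2))
  ages <- vapply(cohort, function(su) su$age_months, numeric(1))
  ofcs <- vapply(cohort, function(su) su$ground_truth$ofc, numeric(1))
  icvs <- vapply(cohort, function(su) su$ground_truth$icv, numeric(1))
  expect_gt(cor(ages, ofcs, method = "spearman"), 0.9)
  expect_gt(cor(ages, icvs, method = "spearman"), 0.9)
})

test_that("reference tables are self-consistent and recover planted offsets", {
  # trivial: sd column constant 2, value mean + 2 -> z = 1
  ref <- growth_reference(data.frame(age_months = c(6, 12), mean = c(40, 44),
                                     sd = c(2, 2)), "ofc", "male")
  expect_equal(z_score(44 + 2, 12, "male", ref), 1)
  # ground-truth self-consistency: cohort from the same growth model scores
  # ~0 against its generated table (analytic values, no mesh in the loop)
  refs <- generate_reference_set(n_mc = 1500, seed = 7)
  cohort <- generate_cohort(cohort_spec("norm", 60, age_range_months = c(6, 66),
                                        mesh_resolution = 1, seed = 3))
  z0 <- vapply(cohort, function(su)
    z_score(su$ground_truth$ofc, su$age_months, "male", refs$ofc$male),
    numeric(1))
  expect_lt(abs(mean(z0)), 0.15)
  # planted +1 SD offset in size
  p1 <- cohort_preset("normocephalic"); p1$ofc_offset_sd <- 1
  shifted <- generate_cohort(cohort_spec("norm+1", 60,
                                         age_range_months = c(6, 66),
                                         params = p1, mesh_resolution = 1,
                                         seed = 3))
  z1 <- vapply(shifted, function(su)
    z_score(su$ground_truth$ofc, su$age_months, "male", refs$ofc$male),
    numeric(1))
  expect_lt(abs(mean(z1) - 1), 0.15)
  expect_error(generate_reference_table(ages = c(12, 12)), "increasing")
})

test_that("invalid head specs are rejected", {
  expect_error(head_spec(length_mm = -1), "length_mm")
  expect_error(head_spec(vertex_flattening = 1.2), "vertex_flattening")
  expect_error(cohort_spec("g", 0), "n_subjects")
})
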