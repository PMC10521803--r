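# Synthetic head surfaces with known ground truth. The family is an
# ellipsoid (upper cranial half of full height, shallow lower cap) deformed
# by radial Gaussian bumps: frontal bossing (anterior-superior), an occipital
# bullet (posterior, just above the reference plane) and a vertex indentation
# (flattening). Because every deformation is radial, the surface stays
# star-shaped about the origin and its contours and volume have cheap
# analytic quadrature ground truth.

# fixed bump geometry (unit directions and angular widths, radians)
BUMP_FRONTAL  <- c(0, 1, 1) / sqrt(2)          # anterior-superior, 45 deg up
BUMP_OCCIPITAL <- c(0, -1, 0.27) / vnorm(c(0, -1, 0.27))  # z ~ 25 mm on a 95 mm head
BUMP_VERTEX   <- c(0, 0, 1)
SIGMA_FRONTAL <- 0.50
SIGMA_OCCIPITAL <- 0.45
SIGMA_VERTEX  <- 0.60

#' Specify a synthetic head
#'
#' @param length_mm Anteroposterior full axis (mm).
#' @param width_mm Transverse full axis (mm).
#' @param height_mm Reference-plane-to-vertex height (mm).
#' @param frontal_bossing Radial bump amplitude at the anterior-superior pole
#'   (mm, >= 0).
#' @param occipital_bullet Radial bump amplitude at the posterior pole just
#'   above the reference plane (mm, >= 0).
#' @param bullet_width Angular width (Gaussian sigma, radians) of the
#'   occipital bullet; the default 0.45 gives a broad residual bullet, small
#'   values give a tight protrusion whose maximum-OFD slice sits well above
#'   the reference plane.
#' @param vertex_flattening Fraction of `height_mm` indented at the vertex
#'   (in `[0, 1)`).
#' @param noise_sd_mm Per-coordinate Gaussian vertex noise SD (mm).
#' @param rigid_perturbation Optional [rigid_transform()] applied to the
#'   generated mesh and landmarks (not to the ground truth).
#' @param mesh_resolution Icosphere subdivision level (default 4: 2562
#'   vertices, 5120 faces).
#' @param seed Integer seed for the vertex noise.
#' @return An object of class `head_spec`.
#' @export
head_spec <- function(length_mm = 180, width_mm = 144, height_mm = 110,
                      frontal_bossing = 0, occipital_bullet = 0,
                      bullet_width = SIGMA_OCCIPITAL,
                      vertex_flattening = 0, noise_sd_mm = 0,
                      rigid_perturbation = NULL, mesh_resolution = 4L,
                      seed = 1L) {
  stopifnot(length_mm > 0, width_mm > 0, height_mm > 0,
            frontal_bossing >= 0, occipital_bullet >= 0, bullet_width > 0,
            vertex_flattening >= 0, vertex_flattening < 1,
            noise_sd_mm >= 0, mesh_resolution >= 1L)
  if (!is.null(rigid_perturbation))
    stopifnot(inherits(rigid_perturbation, "rigid_transform"))
  structure(list(length_mm = length_mm, width_mm = width_mm,
                 height_mm = height_mm, frontal_bossing = frontal_bossing,
                 occipital_bullet = occipital_bullet,
                 bullet_width = bullet_width,
                 vertex_flattening = vertex_flattening,
                 noise_sd_mm = noise_sd_mm,
                 rigid_perturbation = rigid_perturbation,
                 mesh_resolution = as.integer(mesh_resolution),
                 seed = as.integer(seed)),
            class = "head_spec")
}

# ---- icosphere ----

icosphere <- function(subdiv = 4L) {
  phi <- (1 + sqrt(5)) / 2
  v <- rbind(
    c(-1,  phi, 0), c(1,  phi, 0), c(-1, -phi, 0), c(1, -phi, 0),
    c(0, -1,  phi), c(0, 1,  phi), c(0, -1, -phi), c(0, 1, -phi),
    c( phi, 0, -1), c(phi, 0, 1), c(-phi, 0, -1), c(-phi, 0, 1))
  v <- v / sqrt(rowSums(v^2))
  f <- rbind(
    c(1, 12, 6), c(1, 6, 2), c(1, 2, 8), c(1, 8, 11), c(1, 11, 12),
    c(2, 6, 10), c(6, 12, 5), c(12, 11, 3), c(11, 8, 7), c(8, 2, 9),
    c(4, 10, 5), c(4, 5, 3), c(4, 3, 7), c(4, 7, 9), c(4, 9, 10),
    c(5, 10, 6), c(3, 5, 12), c(7, 3, 11), c(9, 7, 8), c(10, 9, 2))
  for (lev in seq_len(subdiv)) {
    nv <- nrow(v)
    # vectorised midpoint construction: collect unique edges first
    e <- rbind(f[, c(1, 2)], f[, c(2, 3)], f[, c(3, 1)])
    ek <- cbind(pmin(e[, 1], e[, 2]), pmax(e[, 1], e[, 2]))
    key <- paste0(ek[, 1], "_", ek[, 2])
    ukey <- unique(key)
    idx <- match(key, ukey)
    ue <- ek[!duplicated(key), , drop = FALSE]
    mids <- (v[ue[, 1], , drop = FALSE] + v[ue[, 2], , drop = FALSE])
    mids <- mids / sqrt(rowSums(mids^2))
    v <- rbind(v, mids)
    m12 <- nv + idx[seq_len(nrow(f))]
    m23 <- nv + idx[nrow(f) + seq_len(nrow(f))]
    m31 <- nv + idx[2L * nrow(f) + seq_len(nrow(f))]
    f <- rbind(cbind(f[, 1], m12, m31),
               cbind(f[, 2], m23, m12),
               cbind(f[, 3], m31, m23),
               cbind(m12, m23, m31))
  }
  mesh <- cranio_mesh(v, f)
  # guarantee outward orientation
  if (mesh_signed_volume(mesh) < 0) mesh$faces <- mesh$faces[, c(1, 3, 2)]
  mesh
}

mesh_signed_volume <- function(mesh) {
  v <- mesh$vertices; f <- mesh$faces
  p1 <- v[f[, 1], , drop = FALSE]; p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  sum(p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
      p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
      p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])) / 6
}

# ---- analytic surface ----

# Radius of the synthetic surface along unit direction(s) d (n x 3 matrix):
# piecewise-ellipsoid radius (full height above the plane, shallow cap below)
# plus the radial Gaussian bumps.
head_radius <- function(d, spec) {
  d <- rbind(d)
  a <- spec$width_mm / 2; b <- spec$length_mm / 2
  cz <- ifelse(d[, 3] >= 0, spec$height_mm, 0.35 * spec$height_mm)
  re <- 1 / sqrt((d[, 1] / a)^2 + (d[, 2] / b)^2 + (d[, 3] / cz)^2)
  bump <- function(center, sigma, amp) {
    if (amp == 0) return(0)
    ang <- acos(pmin(1, pmax(-1, as.numeric(d %*% center))))
    amp * exp(-ang^2 / (2 * sigma^2))
  }
  re +
    bump(BUMP_FRONTAL, SIGMA_FRONTAL, spec$frontal_bossing) +
    bump(BUMP_OCCIPITAL, spec$bullet_width, spec$occipital_bullet) -
    bump(BUMP_VERTEX, SIGMA_VERTEX, spec$vertex_flattening * spec$height_mm)
}

# Analytic contour of the surface at the reference plane z = 0: directions
# (cos t, sin t, 0) hit the plane exactly, so r(t) = head_radius there.
analytic_plane_contour <- function(spec, n = 4096) {
  t <- 2 * pi * (seq_len(n) - 1) / n
  d <- cbind(cos(t), sin(t), 0)
  r <- head_radius(d, spec)
  cbind(r * cos(t), r * sin(t))
}

# Analytic volume above z = 0 via V = (1/3) int r^3 sin(phi) dphi dtheta
# (star-shaped surface, radial parameterisation); trapezoid product grid.
analytic_upper_volume_cc <- function(spec, n_theta = 720, n_phi = 360) {
  theta <- 2 * pi * (seq_len(n_theta) - 0.5) / n_theta
  phi <- (pi / 2) * (seq_len(n_phi) - 0.5) / n_phi
  dtheta <- 2 * pi / n_theta; dphi <- (pi / 2) / n_phi
  total <- 0
  for (ph in phi) {
    d <- cbind(sin(ph) * cos(theta), sin(ph) * sin(theta), cos(ph))
    r <- head_radius(d, spec)
    total <- total + sum(r^3) * sin(ph) * dtheta * dphi
  }
  total / 3 / 1000
}

# Ground-truth measurements from the analytic generator (pre-noise,
# pre-perturbation), evaluated on the reference-plane contour.
analytic_ground_truth <- function(spec, age_months = NA_real_,
                                  sex = NA_character_) {
  p <- analytic_plane_contour(spec)
  ofd <- diff(range(p[, 2]))
  bpd <- diff(range(p[, 1]))
  ofc <- polygon_perimeter(p)
  cephalo_record(ofd, bpd, ofc, 100 * bpd / ofd,
                 icv = analytic_upper_volume_cc(spec),
                 age_months = age_months, sex = sex, slice_z = 0)
}

# run expr with a private RNG stream, restoring the caller's state
with_seed <- function(seed, expr) {
  has <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  expr
}

#' Generate a synthetic head mesh with ground truth
#'
#' Builds a watertight closed surface from an icosphere mapped through the
#' analytic radius function, adds seeded vertex noise and the optional rigid
#' perturbation, and places the three landmarks analytically on the z = 0
#' plane (nasion at the +y extreme, tragi at the +/-x extremes). The ground
#' truth record is computed from the analytic generator before noise and
#' perturbation.
#'
#' @param spec A [head_spec()].
#' @param age_months,sex Carried into the ground-truth record and mesh
#'   metadata.
#' @return A list with elements `mesh`, `landmarks`, `ground_truth`, `spec`.
#' @export
generate_head <- function(spec, age_months = NA_real_, sex = NA_character_) {
  stopifnot(inherits(spec, "head_spec"))
  base <- icosphere(spec$mesh_resolution)
  u <- base$vertices
  a <- spec$width_mm / 2; b <- spec$length_mm / 2
  cz <- ifelse(u[, 3] >= 0, spec$height_mm, 0.35 * spec$height_mm)
  p0 <- cbind(a * u[, 1], b * u[, 2], cz * u[, 3])
  rn <- sqrt(rowSums(p0^2))
  d <- p0 / rn
  r <- head_radius(d, spec)
  v <- d * r
  if (spec$noise_sd_mm > 0)
    v <- v + with_seed(spec$seed,
                       matrix(stats::rnorm(length(v), 0, spec$noise_sd_mm),
                              ncol = 3))
  lm <- cranio_landmarks(
    nasion = c(0, head_radius(c(0, 1, 0), spec), 0),
    tragus_left = c(-head_radius(c(-1, 0, 0), spec), 0, 0),
    tragus_right = c(head_radius(c(1, 0, 0), spec), 0, 0))
  mesh <- cranio_mesh(v, base$faces,
                      metadata = list(synthetic = TRUE, seed = spec$seed,
                                      age_months = age_months, sex = sex))
  if (!is.null(spec$rigid_perturbation)) {
    mesh <- apply_transform(mesh, spec$rigid_perturbation)
    lm <- transform_landmarks(lm, spec$rigid_perturbation)
  }
  list(mesh = mesh, landmarks = lm,
       ground_truth = analytic_ground_truth(spec, age_months, sex),
       spec = spec)
}

#' A seeded random rigid transform (for perturbation tests)
#' @param seed Integer seed.
#' @param max_translation_mm Translation bound per axis.
#' @return A [rigid_transform()].
#' @export
random_rigid_transform <- function(seed, max_translation_mm = 100) {
  with_seed(seed, {
    # uniform random rotation via QR of a Gaussian matrix
    q <- qr.Q(qr(matrix(stats::rnorm(9), 3)))
    if (det(q) < 0) q[, 1] <- -q[, 1]
    rigid_transform(q, stats::runif(3, -max_translation_mm, max_translation_mm))
  })
}

# ---- growth model & cohorts ----

# Default growth curves (months -> mm). Head length rises steeply in the
# first year and saturates; width and height follow via cephalic index and a
# fixed height ratio.
growth_length_mm <- function(age_months) 190 - 72 * exp(-age_months / 14)

default_growth_params <- function() {
  list(ci_mean = 80, ci_sd = 3, size_cv = 0.03, height_ratio = 0.62,
       height_cv = 0.02, frontal_bossing_mean = 0, frontal_bossing_sd = 0,
       occipital_bullet_mean = 0, occipital_bullet_sd = 0,
       vertex_flattening = 0, noise_sd_mm = 0.2, ofc_offset_sd = 0)
}

#' Cohort presets
#'
#' Parameter sets for the morphologies discussed in scaphocephaly follow-up:
#' `"normocephalic"` controls, untreated-like `"scaphocephalic"` heads
#' (elongated and narrow with frontal bossing and an occipital bullet), and
#' three `"postop_*"` groups with near-normal proportions and small residual
#' deformities.
#'
#' @param name Preset name.
#' @return Named list of growth/shape parameters.
#' @export
cohort_preset <- function(name = c("normocephalic", "scaphocephalic",
                                   "postop_FBR", "postop_ESC", "postop_SAC")) {
  name <- match.arg(name)
  p <- default_growth_params()
  mods <- switch(name,
    normocephalic = list(),
    scaphocephalic = list(ci_mean = 68, frontal_bossing_mean = 2,
                          frontal_bossing_sd = 0.5, occipital_bullet_mean = 3,
                          occipital_bullet_sd = 0.8, vertex_flattening = 0.05),
    postop_FBR = list(ci_mean = 76, frontal_bossing_mean = 0.5,
                      frontal_bossing_sd = 0.3, occipital_bullet_mean = 1,
                      occipital_bullet_sd = 0.4, vertex_flattening = 0.03),
    postop_ESC = list(ci_mean = 75, frontal_bossing_mean = 1,
                      frontal_bossing_sd = 0.4, occipital_bullet_mean = 1.2,
                      occipital_bullet_sd = 0.4, vertex_flattening = 0.04),
    postop_SAC = list(ci_mean = 75, frontal_bossing_mean = 1,
                      frontal_bossing_sd = 0.4, occipital_bullet_mean = 1.5,
                      occipital_bullet_sd = 0.5, vertex_flattening = 0.04))
  p[names(mods)] <- mods
  p
}

#' Specify a synthetic cohort
#'
#' @param group_label Free-text group label.
#' @param n_subjects Number of subjects (>= 1).
#' @param age_range_months Length-2 ages (months); subjects drawn uniformly.
#' @param sex_ratio_male Probability a subject is male.
#' @param params Growth/shape parameter list (see [cohort_preset()]).
#' @param mesh_resolution Icosphere subdivision per subject.
#' @param seed Integer master seed for all subject draws.
#' @return An object of class `cohort_spec`.
#' @export
cohort_spec <- function(group_label, n_subjects, age_range_months = c(12, 36),
                        sex_ratio_male = 0.5,
                        params = cohort_preset("normocephalic"),
                        mesh_resolution = 4L, seed = 1L) {
  stopifnot(n_subjects >= 1, length(age_range_months) == 2,
            sex_ratio_male >= 0, sex_ratio_male <= 1)
  bad <- vapply(params[grepl("_sd$|_cv$", names(params))],
                function(x) x < 0, logical(1))
  if (any(bad)) stop("parameter SDs must be >= 0", call. = FALSE)
  structure(list(group_label = group_label, n_subjects = as.integer(n_subjects),
                 age_range_months = as.numeric(age_range_months),
                 sex_ratio_male = sex_ratio_male, params = params,
                 mesh_resolution = as.integer(mesh_resolution),
                 seed = as.integer(seed)),
            class = "cohort_spec")
}

# Relative SD of OFC under the cohort model: the size factor contributes its
# CV directly, and the independent cephalic-index draw adds width variation.
# Computed by a deterministic Monte-Carlo over the parameter distributions;
# used to express a planted cohort offset in reference-table SD units
# (OFC scales linearly with the size factor, so a relative mean shift of
# k * sd(ofc)/mean(ofc) plants a +k z-score shift).
ofc_relative_sd <- function(p, age = 36, n = 4000) {
  with_seed(1234L, {
    s <- stats::rnorm(n, 1, p$size_cv)
    ci <- stats::rnorm(n, p$ci_mean, p$ci_sd)
    len <- growth_length_mm(age) * s
    ofc <- ellipse_perimeter(len / 2, ci / 100 * len / 2)
    stats::sd(ofc) / mean(ofc)
  })
}

# Draw per-subject shape parameters from the cohort distributions. The joint
# size factor scales length/width/height together, so circumference and
# volume are strongly coupled across subjects (as in real growth data);
# ofc_offset_sd shifts the whole cohort by that many reference-table OFC SDs.
draw_subject_params <- function(p, age, ofc_rel_sd = NULL) {
  if (is.null(ofc_rel_sd)) ofc_rel_sd <- ofc_relative_sd(p)
  s <- stats::rnorm(1, 1 + p$ofc_offset_sd * ofc_rel_sd, p$size_cv)
  len <- growth_length_mm(age) * s
  ci <- stats::rnorm(1, p$ci_mean, p$ci_sd)
  list(length_mm = len,
       width_mm = ci / 100 * len,
       height_mm = p$height_ratio * len * (1 + stats::rnorm(1, 0, p$height_cv)),
       frontal_bossing = max(0, stats::rnorm(1, p$frontal_bossing_mean,
                                             p$frontal_bossing_sd)),
       occipital_bullet = max(0, stats::rnorm(1, p$occipital_bullet_mean,
                                              p$occipital_bullet_sd)),
       vertex_flattening = p$vertex_flattening,
       noise_sd_mm = p$noise_sd_mm)
}

#' Generate a synthetic cohort
#'
#' Draws per-subject head specs from the cohort distributions (all
#' randomness governed by the single master seed) and generates each head
#' with its analytic ground truth. Length, width and height increase
#' monotonically with age through the growth model.
#'
#' @param spec A [cohort_spec()].
#' @return List of subjects, each a [generate_head()] result plus `age_months`
#'   and `sex`.
#' @export
generate_cohort <- function(spec) {
  stopifnot(inherits(spec, "cohort_spec"))
  ofc_rel_sd <- ofc_relative_sd(spec$params)
  subjects <- with_seed(spec$seed, {
    lapply(seq_len(spec$n_subjects), function(i) {
      age <- stats::runif(1, spec$age_range_months[1], spec$age_range_months[2])
      sex <- if (stats::runif(1) < spec$sex_ratio_male) "male" else "female"
      pars <- draw_subject_params(spec$params, age, ofc_rel_sd)
      sub_seed <- sample.int(2^30, 1)
      list(age = age, sex = sex, pars = pars, sub_seed = sub_seed)
    })
  })
  lapply(subjects, function(su) {
    hs <- head_spec(length_mm = su$pars$length_mm, width_mm = su$pars$width_mm,
                    height_mm = su$pars$height_mm,
                    frontal_bossing = su$pars$frontal_bossing,
                    occipital_bullet = su$pars$occipital_bullet,
                    vertex_flattening = su$pars$vertex_flattening,
                    noise_sd_mm = su$pars$noise_sd_mm,
                    mesh_resolution = spec$mesh_resolution, seed = su$sub_seed)
    out <- generate_head(hs, age_months = su$age, sex = su$sex)
    out$age_months <- su$age
    out$sex <- su$sex
    out$group_label <- spec$group_label
    out
  })
}

#' Generate a synthetic growth-reference table
#'
#' Monte-Carlo stand-in for the published normocephalic reference tables:
#' at each tabulated age, subject parameters are drawn from the (bump-free)
#' growth model and the measurement computed in closed form — Ramanujan
#' ellipse perimeter for OFC, `100*W/L` for cephalic index, the
#' half-ellipsoid volume for ICV — giving the age-specific mean and SD.
#' Clearly synthetic: not the published Talma / Waitzman / Abbott data.
#'
#' @param params Growth parameter list (bumps ignored; see ledgered design
#'   note in the vignette).
#' @param ages Strictly increasing ages in months.
#' @param sex `"male"` or `"female"` (label only; the default model is
#'   sex-symmetric).
#' @param measurement One of `"ofc"`, `"cephalic_index"`, `"icv"`.
#' @param n_mc Monte-Carlo draws per age.
#' @param seed Seed for the draws.
#' @return A [growth_reference()] labelled `"synthetic"`.
#' @export
generate_reference_table <- function(params = cohort_preset("normocephalic"),
                                     ages = seq(0, 72, by = 3), sex = "male",
                                     measurement = c("ofc", "cephalic_index", "icv"),
                                     n_mc = 2000, seed = 99L) {
  measurement <- match.arg(measurement)
  if (any(diff(ages) <= 0)) stop("ages must be strictly increasing", call. = FALSE)
  rows <- with_seed(seed, {
    lapply(ages, function(age) {
      s <- stats::rnorm(n_mc, 1, params$size_cv)
      len <- growth_length_mm(age) * s
      ci <- stats::rnorm(n_mc, params$ci_mean, params$ci_sd)
      wid <- ci / 100 * len
      hei <- params$height_ratio * len * (1 + stats::rnorm(n_mc, 0, params$height_cv))
      vals <- switch(measurement,
        ofc = ellipse_perimeter(len / 2, wid / 2),
        cephalic_index = ci,
        icv = (2 / 3) * pi * (len / 2) * (wid / 2) * hei / 1000)
      data.frame(age_months = age, mean = mean(vals), sd = stats::sd(vals))
    })
  })
  growth_reference(do.call(rbind, rows), measurement, sex,
                   source_label = "synthetic")
}

#' Generate the full nested reference list for [measure_head()]
#' @inheritParams generate_reference_table
#' @return Nested list `refs[[measurement]][[sex]]`.
#' @export
generate_reference_set <- function(params = cohort_preset("normocephalic"),
                                   ages = seq(0, 72, by = 3),
                                   n_mc = 2000, seed = 99L) {
  refs <- list()
  for (m in c("ofc", "cephalic_index", "icv")) {
    refs[[m]] <- list()
    for (s in c("male", "female"))
      refs[[m]][[s]] <- generate_reference_table(params, ages, s, m, n_mc, seed)
  }
  refs
}
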