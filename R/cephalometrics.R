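# Photocephalometric measurements: occipitofrontal diameter (OFD), biparietal
# diameter (BPD), occipitofrontal circumference (OFC), cephalic index,
# corrected intracranial volume (ICV), growth-reference z-scores, and the
# end-to-end per-scan pipeline.

require_closed <- function(contour) {
  if (!inherits(contour, "planar_contour") || !isTRUE(contour$closed))
    stop("measurement requires a closed planar contour", call. = FALSE)
}

#' Maximum occipitofrontal diameter of an axial contour
#'
#' The anteroposterior extent (max y - min y) in the registered frame, where
#' +y is anterior. A rotating-calipers maximum chord is available with
#' `method = "calipers"` for sensitivity analysis; the axis-aligned extent is
#' the clinical head length and the default.
#'
#' @param contour A closed axial [planar_contour()] in the registered frame.
#' @param method `"extent"` (default) or `"calipers"`.
#' @return Length in mm.
#' @export
measure_ofd <- function(contour, method = c("extent", "calipers")) {
  require_closed(contour)
  method <- match.arg(method)
  if (method == "extent") return(diff(range(contour$points[, 2])))
  max_chord(contour_local_2d(contour))
}

#' Biparietal diameter of an axial contour
#'
#' The transverse extent (max x - min x) in the registered frame.
#'
#' @inheritParams measure_ofd
#' @return Length in mm.
#' @export
measure_bpd <- function(contour, method = c("extent", "calipers")) {
  require_closed(contour)
  method <- match.arg(method)
  if (method == "extent") return(diff(range(contour$points[, 1])))
  max_chord(contour_local_2d(contour))
}

# brute-force maximum pairwise distance (contours have a few hundred points)
max_chord <- function(p2) {
  d2 <- as.matrix(stats::dist(p2))
  max(d2)
}

#' Occipitofrontal head circumference
#'
#' Perimeter of the closed contour, closing segment included.
#'
#' @param contour A closed [planar_contour()].
#' @return Length in mm.
#' @export
measure_ofc <- function(contour) {
  require_closed(contour)
  contour_perimeter(contour)
}

#' Cephalic index
#'
#' `100 * bpd / ofd`: the head width as a percentage of head length. Values
#' well below ~75 indicate scaphocephaly.
#'
#' @param bpd Biparietal diameter (mm).
#' @param ofd Occipitofrontal diameter (mm).
#' @return Percent.
#' @export
cephalic_index <- function(bpd, ofd) {
  if (!is.finite(ofd) || ofd <= 0) stop("ofd must be positive", call. = FALSE)
  100 * bpd / ofd
}

#' Construct an ICV correction
#'
#' Photogrammetric volumes overestimate the intracranial volume (the scan
#' surface includes scalp and cap); the correction is the linear map
#' `corrected = slope * raw + intercept` calibrated against CT volumes.
#' The identity correction (slope 1, intercept 0) is the uncalibrated
#' default — no literature constant is shipped as truth.
#'
#' @param slope Dimensionless slope (> 0).
#' @param intercept Intercept in cc.
#' @param r_squared Coefficient of determination of the calibration fit.
#' @param n_pairs Number of calibration pairs.
#' @return An object of class `icv_correction`.
#' @export
icv_correction <- function(slope = 1, intercept = 0, r_squared = NA_real_,
                           n_pairs = 0L) {
  if (!is.finite(slope) || slope <= 0) stop("slope must be > 0", call. = FALSE)
  if (is.finite(r_squared) && (r_squared < 0 || r_squared > 1))
    stop("r_squared must be in [0, 1]", call. = FALSE)
  structure(list(slope = slope, intercept = intercept,
                 r_squared = r_squared, n_pairs = as.integer(n_pairs)),
            class = "icv_correction")
}

#' @export
print.icv_correction <- function(x, ...) {
  cat(sprintf("<icv_correction> corrected = %.4f * raw %+.1f cc (R^2 = %s, n = %d)\n",
              x$slope, x$intercept,
              if (is.finite(x$r_squared)) sprintf("%.3f", x$r_squared) else "NA",
              x$n_pairs))
  invisible(x)
}

#' Calibrate the photogrammetry-to-CT volume correction
#'
#' Ordinary least-squares fit `ct = slope * raw + intercept` on paired
#' volumes from scans acquired the same day.
#'
#' @param raw Photogrammetric volumes (cc), or a 2-column data.frame/matrix
#'   of (raw, ct) pairs.
#' @param ct CT volumes (cc); omit when `raw` holds both columns.
#' @return An [icv_correction()] with `r_squared` and `n_pairs` filled in.
#' @export
calibrate_icv_correction <- function(raw, ct = NULL) {
  if (is.null(ct)) {
    raw <- as.data.frame(raw)
    ct <- raw[[2]]; raw <- raw[[1]]
  }
  if (length(raw) != length(ct) || length(raw) < 3)
    stop("need at least 3 calibration pairs", call. = FALSE)
  if (stats::sd(raw) < 1e-9)
    stop("degenerate calibration: all raw volumes equal", call. = FALSE)
  fit <- stats::lm(ct ~ raw)
  icv_correction(slope = unname(stats::coef(fit)[2]),
                 intercept = unname(stats::coef(fit)[1]),
                 r_squared = summary(fit)$r.squared,
                 n_pairs = length(raw))
}

#' Estimate the (corrected) intracranial volume
#'
#' Computes the volume enclosed by the cranial portion of a watertight
#' registered mesh above the nasion-tragi plane z = 0, by the divergence
#' theorem with F = (0, 0, z): crossing triangles are clipped to the
#' half-space z >= 0 and the planar cut itself contributes zero flux, so no
#' explicit cap triangulation is needed. The raw mm^3 volume is converted to
#' cc and passed through the linear correction.
#'
#' @param mesh A registered, watertight [cranio_mesh()].
#' @param correction An [icv_correction()]; identity by default.
#' @return Corrected volume in cc, with the raw volume as attribute `"raw_cc"`.
#' @export
estimate_icv <- function(mesh, correction = icv_correction()) {
  stopifnot(inherits(mesh, "cranio_mesh"), inherits(correction, "icv_correction"))
  rep_ <- validate_mesh(mesh)
  if (!rep_$watertight)
    stop("volume error: mesh is not watertight", call. = FALSE)
  v <- mesh$vertices; f <- mesh$faces

  # global orientation from the full-mesh signed volume
  p1 <- v[f[, 1], , drop = FALSE]; p2 <- v[f[, 2], , drop = FALSE]
  p3 <- v[f[, 3], , drop = FALSE]
  det6 <- p1[, 1] * (p2[, 2] * p3[, 3] - p2[, 3] * p3[, 2]) -
          p1[, 2] * (p2[, 1] * p3[, 3] - p2[, 3] * p3[, 1]) +
          p1[, 3] * (p2[, 1] * p3[, 2] - p2[, 2] * p3[, 1])
  orient <- sign(sum(det6))
  if (orient == 0) stop("volume error: degenerate mesh orientation", call. = FALSE)

  flux_tri <- function(a, b, c3) {
    n <- cross3(b - a, c3 - a)           # 2 * area * unit normal
    n[3] / 2 * (a[3] + b[3] + c3[3]) / 3 # integral of z * nz over triangle
  }

  z <- matrix(v[, 3][f], ncol = 3L)
  above <- z >= 0
  n_above <- rowSums(above)
  total <- 0
  full <- which(n_above == 3L)
  if (length(full)) {
    a <- v[f[full, 1], , drop = FALSE]; b <- v[f[full, 2], , drop = FALSE]
    c3 <- v[f[full, 3], , drop = FALSE]
    nz <- (b[, 1] - a[, 1]) * (c3[, 2] - a[, 2]) -
          (b[, 2] - a[, 2]) * (c3[, 1] - a[, 1])
    total <- sum(nz / 2 * (a[, 3] + b[, 3] + c3[, 3]) / 3)
  }
  partial <- which(n_above %in% c(1L, 2L))
  for (fi in partial) {
    tri <- v[f[fi, ], , drop = FALSE]
    poly <- clip_triangle_above_z0(tri)
    if (is.null(poly) || nrow(poly) < 3L) next
    for (k in 2:(nrow(poly) - 1L))
      total <- total + flux_tri(poly[1, ], poly[k, ], poly[k + 1L, ])
  }
  raw_cc <- abs(orient * total) / 1000
  corrected <- correction$slope * raw_cc + correction$intercept
  if (corrected < 0) stop("domain error: corrected volume is negative", call. = FALSE)
  structure(corrected, raw_cc = raw_cc)
}

# Sutherland-Hodgman clip of one triangle against the half-space z >= 0,
# preserving the input winding. Returns a 3- or 4-gon (or NULL).
clip_triangle_above_z0 <- function(tri) {
  out <- list()
  for (i in 1:3) {
    a <- tri[i, ]; b <- tri[if (i == 3L) 1L else i + 1L, ]
    ina <- a[3] >= 0; inb <- b[3] >= 0
    if (ina) out[[length(out) + 1L]] <- a
    if (xor(ina, inb)) {
      t <- a[3] / (a[3] - b[3])
      out[[length(out) + 1L]] <- a + t * (b - a)
    }
  }
  if (!length(out)) return(NULL)
  do.call(rbind, out)
}

#' Construct a growth-reference table
#'
#' Age- and sex-specific normocephalic means and SDs for one measurement.
#' Real reference tables (head circumference, cephalic index, intracranial
#' volume) are supplied by the user as CSV; the tables produced by
#' [generate_reference_table()] are synthetic stand-ins.
#'
#' @param table Data frame with columns `age_months`, `mean`, `sd` (ages
#'   strictly increasing, sd > 0).
#' @param measurement_name One of `"ofc"`, `"cephalic_index"`, `"icv"`.
#' @param sex `"male"` or `"female"`.
#' @param source_label Free-text provenance label.
#' @return An object of class `growth_reference`.
#' @export
growth_reference <- function(table, measurement_name, sex,
                             source_label = "user") {
  measurement_name <- match.arg(measurement_name, c("ofc", "cephalic_index", "icv"))
  sex <- match.arg(sex, c("male", "female"))
  table <- as.data.frame(table)[, c("age_months", "mean", "sd")]
  if (any(diff(table$age_months) <= 0))
    stop("reference ages must be strictly increasing", call. = FALSE)
  if (any(table$sd <= 0)) stop("reference sd must be positive", call. = FALSE)
  structure(list(table = table, measurement_name = measurement_name,
                 sex = sex, source_label = source_label),
            class = "growth_reference")
}

#' Read growth references from CSV
#'
#' Schema: `measurement,sex,age_months,mean,sd`. Returns a nested list
#' `refs[[measurement]][[sex]]` of [growth_reference()] objects, the
#' structure [measure_head()] expects.
#'
#' @param path CSV path.
#' @param source_label Provenance label stored on each table.
#' @return Nested list of growth references.
#' @export
read_growth_references <- function(path, source_label = path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("measurement", "sex", "age_months", "mean", "sd")
  if (!all(need %in% names(df)))
    stop("growth-reference CSV needs columns ", paste(need, collapse = ","),
         call. = FALSE)
  refs <- list()
  for (m in unique(df$measurement)) {
    refs[[m]] <- list()
    for (s in unique(df$sex[df$measurement == m])) {
      sub <- df[df$measurement == m & df$sex == s, ]
      sub <- sub[order(sub$age_months), ]
      refs[[m]][[s]] <- growth_reference(sub, m, s, source_label)
    }
  }
  refs
}

#' Write growth references to CSV
#' @param refs Nested list as returned by [read_growth_references()].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_growth_references <- function(refs, path) {
  rows <- list()
  for (m in names(refs)) for (s in names(refs[[m]])) {
    tb <- refs[[m]][[s]]$table
    rows[[length(rows) + 1L]] <- data.frame(measurement = m, sex = s, tb)
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Convert a measurement to an age/sex z-score
#'
#' `z = (value - mean(age)) / sd(age)` with the reference mean and SD
#' linearly interpolated in age. Ages outside the table range are clamped to
#' the nearest row with a warning.
#'
#' @param value Measured value (same units as the reference table).
#' @param age_months Age in months.
#' @param sex `"male"` or `"female"`; must match the reference table.
#' @param reference A [growth_reference()].
#' @return z-score in SD units.
#' @export
z_score <- function(value, age_months, sex, reference) {
  stopifnot(inherits(reference, "growth_reference"))
  sex <- match.arg(sex, c("male", "female"))
  if (!identical(sex, reference$sex))
    stop("lookup error: reference table is for sex '", reference$sex, "'",
         call. = FALSE)
  tb <- reference$table
  if (age_months < min(tb$age_months) || age_months > max(tb$age_months)) {
    warning(sprintf("age %.1f months outside reference range [%g, %g]; clamped",
                    age_months, min(tb$age_months), max(tb$age_months)),
            call. = FALSE)
    age_months <- min(max(age_months, min(tb$age_months)), max(tb$age_months))
  }
  m <- stats::approx(tb$age_months, tb$mean, xout = age_months, rule = 2)$y
  s <- stats::approx(tb$age_months, tb$sd, xout = age_months, rule = 2)$y
  (value - m) / s
}

#' Construct a cephalometric record
#'
#' One scan's measurements and z-scores. Soft sanity checks emit warnings:
#' OFD should not be smaller than BPD for scaphocephalic or normal heads, and
#' OFC should be at least 90% of the ellipse-perimeter lower bound
#' pi*(OFD+BPD)/2 (degenerate-contour guard).
#'
#' @param ofd,bpd,ofc Lengths in mm.
#' @param cephalic_index Percent (must equal 100*bpd/ofd).
#' @param icv Corrected volume in cc (NA when unavailable).
#' @param z_ofc,z_ci,z_icv z-scores in SD units (NA when no reference).
#' @param age_months Age in months.
#' @param sex `"male"` or `"female"`.
#' @param slice_z z of the selected max-OFD axial slice (mm).
#' @return An object of class `cephalo_record`.
#' @export
cephalo_record <- function(ofd, bpd, ofc, cephalic_index, icv = NA_real_,
                           z_ofc = NA_real_, z_ci = NA_real_, z_icv = NA_real_,
                           age_months = NA_real_,
                           sex = NA_character_, slice_z = NA_real_) {
  if (abs(cephalic_index - 100 * bpd / ofd) > 1e-9)
    stop("cephalic_index inconsistent with 100*bpd/ofd", call. = FALSE)
  if (is.finite(ofd) && is.finite(bpd) && (bpd > ofd || bpd <= 0))
    warning("bpd > ofd or non-positive: unusual head geometry", call. = FALSE)
  if (is.finite(ofc) && ofc < 0.9 * pi * (ofd + bpd) / 2)
    warning("ofc implausibly small for the measured diameters", call. = FALSE)
  structure(list(ofd = ofd, bpd = bpd, ofc = ofc,
                 cephalic_index = cephalic_index, icv = icv,
                 z_ofc = z_ofc, z_ci = z_ci, z_icv = z_icv,
                 age_months = age_months, sex = sex, slice_z = slice_z),
            class = "cephalo_record")
}

#' @export
print.cephalo_record <- function(x, ...) {
  cat("<cephalo_record>\n")
  cat(sprintf("  OFD %.1f mm  BPD %.1f mm  OFC %.1f mm  CI %.1f  ICV %s cc\n",
              x$ofd, x$bpd, x$ofc, x$cephalic_index,
              if (is.finite(x$icv)) sprintf("%.0f", x$icv) else "NA"))
  cat(sprintf("  z(OFC) %s  z(CI) %s  z(ICV) %s   [age %s mo, %s, slice z %.1f mm]\n",
              fmtz(x$z_ofc), fmtz(x$z_ci), fmtz(x$z_icv),
              format(x$age_months), x$sex, x$slice_z))
  invisible(x)
}

fmtz <- function(z) if (is.finite(z)) sprintf("%+.2f", z) else "NA"

#' @export
as.data.frame.cephalo_record <- function(x, ...) {
  data.frame(ofd = x$ofd, bpd = x$bpd, ofc = x$ofc,
             cephalic_index = x$cephalic_index, icv = x$icv,
             z_ofc = x$z_ofc, z_ci = x$z_ci, z_icv = x$z_icv,
             age_months = x$age_months, sex = x$sex, slice_z = x$slice_z,
             stringsAsFactors = FALSE)
}

#' Measure a head scan end to end
#'
#' Runs the full pipeline: registration to the nasion-tragi frame, the
#' iterative max-OFD axial slice search, orthogonal slice extraction, all
#' five measurements, and z-score conversion. Deterministic for fixed
#' inputs.
#'
#' @param mesh A [cranio_mesh()].
#' @param landmarks The matching [cranio_landmarks()].
#' @param age_months Age in months (for z-scores; NA skips them).
#' @param sex `"male"` or `"female"`.
#' @param references Nested list `refs[[measurement]][[sex]]` of
#'   [growth_reference()] tables (see [read_growth_references()]); NULL skips
#'   z-scores.
#' @param correction An [icv_correction()]; identity by default.
#' @param slice_step Axial search step in mm.
#' @param compute_icv Set FALSE to skip volume estimation (e.g. for
#'   non-watertight meshes, which are still valid for contour measurements).
#' @return A [cephalo_record()]; the registered head is attached as
#'   attribute `"registered"` and the axial contour as `"axial_contour"`.
#' @export
measure_head <- function(mesh, landmarks, age_months = NA_real_, sex = "male",
                         references = NULL, correction = icv_correction(),
                         slice_step = 1, compute_icv = TRUE) {
  stage <- function(what, expr) {
    tryCatch(expr, error = function(e)
      stop(sprintf("[%s] %s", what, conditionMessage(e)), call. = FALSE))
  }
  reg <- stage("registration", register_head(mesh, landmarks, slice_step))
  axial <- stage("slice-search",
                 find_max_ofd_slice(reg$mesh, step = slice_step))
  orth <- stage("orthogonal-slices", extract_orthogonal_contours(reg$mesh, axial))
  ofd <- measure_ofd(axial)
  bpd <- measure_bpd(axial)
  ofc <- measure_ofc(axial)
  ci <- cephalic_index(bpd, ofd)
  icv <- if (compute_icv)
    stage("volume", as.numeric(estimate_icv(reg$mesh, correction)))
  else NA_real_
  zs <- c(z_ofc = NA_real_, z_ci = NA_real_, z_icv = NA_real_)
  if (!is.null(references) && is.finite(age_months)) {
    pick <- function(m) {
      r <- references[[m]]
      if (is.null(r)) return(NULL)
      if (inherits(r, "growth_reference")) r else r[[sex]]
    }
    vals <- c(ofc = ofc, cephalic_index = ci, icv = icv)
    keys <- c(ofc = "z_ofc", cephalic_index = "z_ci", icv = "z_icv")
    for (m in names(vals)) {
      ref <- pick(m)
      if (!is.null(ref) && is.finite(vals[[m]]))
        zs[[keys[[m]]]] <- z_score(vals[[m]], age_months, sex, ref)
    }
  }
  rec <- cephalo_record(ofd, bpd, ofc, ci, icv,
                        z_ofc = zs[["z_ofc"]], z_ci = zs[["z_ci"]],
                        z_icv = zs[["z_icv"]],
                        age_months = age_months, sex = sex,
                        slice_z = axial$plane$origin[3])
  attr(rec, "registered") <- reg
  attr(rec, "axial_contour") <- axial
  attr(rec, "orthogonal_contours") <- orth
  rec
}

#' Check OFC as a proxy for ICV
#'
#' Coefficient of determination of the OLS regression `icv ~ ofc` across
#' records, mirroring the verification that head circumference tracks
#' intracranial volume.
#'
#' @param records List of [cephalo_record()]s (or a data.frame with `ofc`
#'   and `icv` columns).
#' @return R-squared.
#' @export
ofc_icv_proxy_check <- function(records) {
  df <- if (is.data.frame(records)) records
        else do.call(rbind, lapply(records, as.data.frame))
  df <- df[is.finite(df$ofc) & is.finite(df$icv), ]
  if (nrow(df) < 3) stop("need at least 3 records with finite ofc and icv",
                         call. = FALSE)
  if (stats::sd(df$ofc) < 1e-9 || stats::sd(df$icv) < 1e-9)
    stop("degenerate variance in ofc or icv", call. = FALSE)
  summary(stats::lm(icv ~ ofc, data = df))$r.squared
}
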