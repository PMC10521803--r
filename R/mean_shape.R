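# Pointwise mean cranial shapes with SD bands, and deviation profiles versus
# a reference shape. Requires the fixed angular correspondence produced by
# resample_contour: sample k always means the same angle in the same
# orientation, so means and SDs are taken per index.

#' Compute a group mean shape with SD band
#'
#' Pointwise over subjects: `mean_points[k]` is the coordinate-wise mean of
#' sample k; `sd_radial[k]` is the sample SD (n-1 denominator; 0 for a single
#' subject) of the subjects' radial distances at index k.
#'
#' @param contours List of `sampled_contour`s sharing `n_samples` and
#'   orientation.
#' @param group_label Free-text label for the group.
#' @return An object of class `mean_shape_model` with fields
#'   `orientation_label`, `mean_points`, `mean_radial`, `sd_radial`,
#'   `n_subjects`, `n_samples`, `group_label`.
#' @export
compute_mean_shape <- function(contours, group_label = "group") {
  if (!length(contours)) stop("empty contour list", call. = FALSE)
  if (!all(vapply(contours, inherits, logical(1), "sampled_contour")))
    stop("all inputs must be sampled contours", call. = FALSE)
  ns <- vapply(contours, function(x) x$n_samples, integer(1))
  ori <- vapply(contours, function(x) x$orientation_label, character(1))
  if (length(unique(ns)) != 1L || length(unique(ori)) != 1L)
    stop("schema error: contours mix sample counts or orientations",
         call. = FALSE)
  n <- ns[1]
  pts <- array(unlist(lapply(contours, function(x) x$points)),
               dim = c(n, 2, length(contours)))
  radii <- vapply(contours, function(x) x$radii, numeric(n))
  radii <- matrix(radii, nrow = n)
  sd_radial <- if (length(contours) == 1L) rep(0, n) else apply(radii, 1, stats::sd)
  structure(list(orientation_label = ori[1],
                 mean_points = apply(pts, c(1, 2), mean),
                 mean_radial = rowMeans(radii),
                 sd_radial = sd_radial,
                 n_subjects = length(contours),
                 n_samples = n,
                 group_label = group_label),
            class = "mean_shape_model")
}

#' @export
print.mean_shape_model <- function(x, ...) {
  cat(sprintf("<mean_shape_model> '%s' %s, %d subjects, %d samples, mean radius %.1f mm (SD band %.1f-%.1f mm)\n",
              x$group_label, x$orientation_label, x$n_subjects, x$n_samples,
              mean(x$mean_radial), min(x$sd_radial), max(x$sd_radial)))
  invisible(x)
}

#' Deviation profile of a group shape versus a reference shape
#'
#' Per sample index: the signed radial difference (group mean radius minus
#' reference mean radius, mm) and, where the reference SD is positive, that
#' difference standardised by the reference SD (z-like units).
#'
#' @param model Group [compute_mean_shape()] result.
#' @param reference Reference mean shape (same orientation and sample count).
#' @return An object of class `shape_deviation_profile` with fields
#'   `deviation_mm`, `deviation_z`, `orientation_label`, `reference_label`.
#' @export
shape_deviation <- function(model, reference) {
  stopifnot(inherits(model, "mean_shape_model"),
            inherits(reference, "mean_shape_model"))
  if (!identical(model$orientation_label, reference$orientation_label) ||
      model$n_samples != reference$n_samples)
    stop("schema error: model and reference orientation/sample mismatch",
         call. = FALSE)
  dev <- model$mean_radial - reference$mean_radial
  z <- ifelse(reference$sd_radial > 0, dev / reference$sd_radial, NA_real_)
  structure(list(deviation_mm = dev, deviation_z = z,
                 orientation_label = model$orientation_label,
                 reference_label = reference$group_label),
            class = "shape_deviation_profile")
}

#' @export
print.shape_deviation_profile <- function(x, ...) {
  cat(sprintf("<shape_deviation_profile> %s vs '%s': deviation %.1f to %.1f mm\n",
              x$orientation_label, x$reference_label,
              min(x$deviation_mm), max(x$deviation_mm)))
  invisible(x)
}

#' Assign follow-up windows by nearest window centre
#'
#' The default windows follow the clinical follow-up scheme: about 3 months
#' after surgery (FU1, centred at 12 months of age here), then 24, 36, 48,
#' 60 and 72 months of age.
#'
#' @param age_months Numeric ages.
#' @param centers Window centres in months.
#' @return Factor of window labels `FU1`..`FUk`.
#' @export
assign_followup_window <- function(age_months,
                                   centers = c(12, 24, 36, 48, 60, 72)) {
  idx <- vapply(age_months, function(a) which.min(abs(centers - a)), integer(1))
  factor(paste0("FU", idx), levels = paste0("FU", seq_along(centers)))
}

#' Write a mean shape to CSV
#'
#' Columns: `angle_deg`, `mean_x`, `mean_y`, `sd_radial`.
#'
#' @param model A [compute_mean_shape()] result.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_mean_shape_csv <- function(model, path) {
  df <- data.frame(
    angle_deg = 360 * (seq_len(model$n_samples) - 1) / model$n_samples,
    mean_x = model$mean_points[, 1], mean_y = model$mean_points[, 2],
    sd_radial = model$sd_radial)
  utils::write.csv(df, path, row.names = FALSE)
  invisible(path)
}
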