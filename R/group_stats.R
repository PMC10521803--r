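# Assumption-gated group comparison: Shapiro-Wilk per group + Levene across
# groups decide between one-way ANOVA (post hoc pairwise t) and
# Kruskal-Wallis (post hoc Conover-Iman), with Bonferroni correction of the
# pairwise p-values. The compared quantity in practice is the z-score, not
# the raw measurement.

check_groups <- function(groups) {
  if (!is.list(groups) || length(groups) < 2)
    stop("need at least 2 groups", call. = FALSE)
  ns <- vapply(groups, length, integer(1))
  if (any(ns < 3))
    stop("insufficient data: every group needs n >= 3", call. = FALSE)
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    names(groups) <- paste0("g", seq_along(groups))
  groups
}

# Levene's test (center = mean, as in the classical formulation): one-way
# ANOVA on the absolute deviations from the group means.
levene_test <- function(groups) {
  z <- unlist(lapply(groups, function(x) abs(x - mean(x))))
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))))
  stats::anova(stats::lm(z ~ g))[["Pr(>F)"]][1]
}

#' Select the omnibus test from the assumption gate
#'
#' One-way ANOVA is selected iff every group passes Shapiro-Wilk normality
#' (p >= alpha) and Levene's homogeneity-of-variance test passes
#' (p >= alpha); otherwise Kruskal-Wallis. The gate p-values are returned
#' for reporting.
#'
#' @param groups Named list of numeric vectors (each n >= 3).
#' @param alpha Gate significance level (default 0.05, same as the
#'   comparison alpha).
#' @return List with `test` (`"anova"` or `"kruskal_wallis"`), `shapiro_p`
#'   (named per group) and `levene_p`.
#' @export
select_test <- function(groups, alpha = 0.05) {
  groups <- check_groups(groups)
  # constant groups make Shapiro-Wilk undefined; treat as failing the gate
  shapiro_p <- vapply(groups, function(x)
    tryCatch(stats::shapiro.test(x)$p.value, error = function(e) 0),
    numeric(1))
  levene_p <- levene_test(groups)
  test <- if (all(shapiro_p >= alpha) && levene_p >= alpha) "anova"
          else "kruskal_wallis"
  list(test = test, shapiro_p = shapiro_p, levene_p = levene_p)
}

#' Conover-Iman post hoc test after Kruskal-Wallis
#'
#' Pooled midranks across all groups; for groups i, j the statistic is
#' `t = (Ri - Rj) / sqrt(S2 * ((N - 1 - H)/(N - k)) * (1/ni + 1/nj))` with
#' Ri the group mean ranks, S2 the variance of all ranks, H the
#' Kruskal-Wallis statistic (tie-corrected), N the total count and k the
#' number of groups; two-sided p from Student's t with N - k degrees of
#' freedom.
#'
#' @param groups Named list of numeric vectors.
#' @return Data frame with columns `group_i`, `group_j`, `statistic`,
#'   `p_raw`, `p_adjusted` (Bonferroni over all pairs).
#' @export
conover_posthoc <- function(groups) {
  groups <- check_groups(groups)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  if (stats::sd(x) < 1e-12)
    stop("degenerate-rank error: all values tied", call. = FALSE)
  r <- rank(x)  # midranks for ties
  N <- length(x); k <- nlevels(g)
  ni <- tabulate(g)
  Ri <- tapply(r, g, mean)
  S2 <- stats::var(r)
  H <- stats::kruskal.test(x, g)$statistic
  scale2 <- S2 * (N - 1 - H) / (N - k)
  pairs <- utils::combn(levels(g), 2)
  out <- data.frame(group_i = pairs[1, ], group_j = pairs[2, ],
                    statistic = NA_real_, p_raw = NA_real_)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    se <- sqrt(scale2 * (1 / ni[match(i, levels(g))] +
                         1 / ni[match(j, levels(g))]))
    tstat <- (Ri[[i]] - Ri[[j]]) / se
    out$statistic[p] <- tstat
    out$p_raw[p] <- 2 * stats::pt(-abs(tstat), df = N - k)
  }
  out$p_adjusted <- pmin(1, out$p_raw * nrow(out))
  out
}

# pooled-SD pairwise t tests (classical ANOVA post hoc)
pairwise_t_posthoc <- function(groups) {
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  ni <- tabulate(g); N <- length(x); k <- nlevels(g)
  means <- tapply(x, g, mean)
  ss_within <- sum(unlist(lapply(groups, function(v) sum((v - mean(v))^2))))
  s2p <- ss_within / (N - k)
  pairs <- utils::combn(levels(g), 2)
  out <- data.frame(group_i = pairs[1, ], group_j = pairs[2, ],
                    statistic = NA_real_, p_raw = NA_real_)
  for (p in seq_len(ncol(pairs))) {
    i <- pairs[1, p]; j <- pairs[2, p]
    se <- sqrt(s2p * (1 / ni[match(i, levels(g))] + 1 / ni[match(j, levels(g))]))
    tstat <- (means[[i]] - means[[j]]) / se
    out$statistic[p] <- tstat
    out$p_raw[p] <- 2 * stats::pt(-abs(tstat), df = N - k)
  }
  out$p_adjusted <- pmin(1, out$p_raw * nrow(out))
  out
}

#' Compare groups with the gated procedure
#'
#' Runs [select_test()], the selected omnibus test (classical one-way ANOVA
#' or Kruskal-Wallis), and — when the omnibus p-value is below alpha — the
#' matching post hoc (pairwise t after ANOVA, Conover-Iman after
#' Kruskal-Wallis), Bonferroni-adjusted over all pairs.
#'
#' @param groups Named list of numeric vectors, or a data.frame plus
#'   `group_col`/`value_col`.
#' @param measurement_name Label carried into the report.
#' @param alpha Significance level (default 0.05).
#' @param group_col,value_col Column names when `groups` is a data.frame.
#' @return An object of class `group_comparison` with fields
#'   `measurement_name`, `groups` (n per group), `gate`, `test_used`,
#'   `omnibus_p`, `posthoc` (NULL unless omnibus significant), `alpha`.
#' @export
compare_groups <- function(groups, measurement_name = "value", alpha = 0.05,
                           group_col = "group", value_col = "value") {
  if (is.data.frame(groups))
    groups <- split(groups[[value_col]], groups[[group_col]])
  groups <- check_groups(groups)
  gate <- select_test(groups, alpha)
  x <- unlist(groups, use.names = FALSE)
  g <- factor(rep(names(groups), vapply(groups, length, integer(1))),
              levels = names(groups))
  if (gate$test == "anova") {
    omnibus_p <- stats::anova(stats::lm(x ~ g))[["Pr(>F)"]][1]
  } else {
    omnibus_p <- stats::kruskal.test(x, g)$p.value
  }
  posthoc <- NULL
  if (is.finite(omnibus_p) && omnibus_p < alpha) {
    posthoc <- if (gate$test == "anova") pairwise_t_posthoc(groups)
               else conover_posthoc(groups)
  }
  structure(list(measurement_name = measurement_name,
                 groups = vapply(groups, length, integer(1)),
                 gate = gate[c("shapiro_p", "levene_p")],
                 test_used = gate$test,
                 omnibus_p = if (is.finite(omnibus_p)) omnibus_p else 1,
                 posthoc = posthoc,
                 alpha = alpha),
            class = "group_comparison")
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("<group_comparison> %s across %d groups (n = %s)\n",
              x$measurement_name, length(x$groups),
              paste(x$groups, collapse = ", ")))
  cat(sprintf("  gate: Shapiro-Wilk min p = %.3g, Levene p = %.3g -> %s\n",
              min(x$gate$shapiro_p), x$gate$levene_p, x$test_used))
  cat(sprintf("  omnibus p = %.4g (alpha = %g)%s\n", x$omnibus_p, x$alpha,
              if (x$omnibus_p < x$alpha) "" else " — not significant, no post hoc"))
  if (!is.null(x$posthoc)) {
    cat("  post hoc (Bonferroni-adjusted):\n")
    print(x$posthoc, row.names = FALSE)
  }
  invisible(x)
}
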