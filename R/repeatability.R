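#' Paired test-retest measurements for one quantitative index
#'
#' @param subject_id subject identifiers (unique).
#' @param m1,m2 the two same-visit measurements per subject.
#' @param index index label (e.g. `"cc_fv"`, `"scp_vd"`).
#' @param units measurement units (default `"mm2"`).
#' @return A data frame of class `paired_measurements`.
#' @export
paired_measurements <- function(subject_id, m1, m2, index = "index", units = "mm2") {
  if (length(m1) != length(m2) || length(subject_id) != length(m1)) {
    stop("subject_id, m1 and m2 must have equal length", call. = FALSE)
  }
  if (anyDuplicated(subject_id)) stop("subject_id values must be unique", call. = FALSE)
  if (!all(is.finite(m1)) || !all(is.finite(m2))) {
    stop("measurements must be finite", call. = FALSE)
  }
  structure(
    data.frame(subject_id = as.character(subject_id), m1 = m1, m2 = m2,
               stringsAsFactors = FALSE),
    index = index, units = units,
    class = c("paired_measurements", "data.frame")
  )
}

#' Bland-Altman agreement analysis
#'
#' Differences are taken as `d = m1 - m2`.  Reports the bias (mean
#' difference), the sample SD of the differences, the coefficient of
#' repeatability CR = 1.96 * SD(d), the 95% limits of agreement
#' bias +/- CR, a one-sample t-test of the differences against zero, and CR
#' as a fraction of the grand mean of the per-subject averages.
#'
#' @param pairs a [paired_measurements()] object (n >= 3).
#' @return A list of class `bland_altman_result`.
#' @export
bland_altman <- function(pairs) {
  stopifnot(inherits(pairs, "paired_measurements"))
  n <- nrow(pairs)
  if (n < 3) stop("Bland-Altman analysis needs at least 3 pairs", call. = FALSE)
  d <- pairs$m1 - pairs$m2
  bias <- mean(d)
  sd_diff <- stats::sd(d)
  cr <- 1.96 * sd_diff
  avg <- (pairs$m1 + pairs$m2) / 2
  grand_mean <- mean(avg)
  degenerate_p <- FALSE
  if (sd_diff < 1e-12) {
    # constant differences: the t statistic is undefined (0/0) or infinite
    p <- if (abs(bias) < 1e-12) NA_real_ else .Machine$double.xmin
    degenerate_p <- abs(bias) >= 1e-12
  } else {
    p <- stats::t.test(d)$p.value
  }
  structure(
    list(n = n, bias = bias, sd_diff = sd_diff, CR = cr,
         loa_lower = bias - cr, loa_upper = bias + cr, p_value = p,
         degenerate_p = degenerate_p, grand_mean = grand_mean,
         sd_of_means = stats::sd(avg),
         cr_over_mean = if (grand_mean > 0) cr / grand_mean else NA_real_),
    class = "bland_altman_result"
  )
}

#' CR as a fraction of the average measurement
#'
#' The coefficient of repeatability divided by the grand mean of all tested
#' subjects — a CV-like variability summary for Bland-Altman output.
#'
#' @param CR coefficient of repeatability.
#' @param grand_mean mean measurement across all subjects (> 0).
#' @return The ratio CR / grand_mean.
#' @export
cr_over_mean <- function(CR, grand_mean) {
  if (grand_mean <= 0) stop("grand mean must be positive", call. = FALSE)
  CR / grand_mean
}

#' Recover the CR implied by published limits of agreement
#'
#' For limits of agreement `bias +/- CR`, the CR equals half the width of the
#' interval, `(upper - lower) / 2` — robust to independent rounding of the
#' printed bias and limits.
#'
#' @param loa_lower,loa_upper 95% limits of agreement.
#' @return The implied coefficient of repeatability.
#' @export
cr_from_loa <- function(loa_lower, loa_upper) {
  if (loa_upper < loa_lower) stop("upper limit below lower limit", call. = FALSE)
  (loa_upper - loa_lower) / 2
}

#' ICC(3,1): two-way mixed-effects, consistency, single measurement
#'
#' Decomposes the paired measurements by two-way ANOVA (subjects random,
#' scan occasion fixed) and returns
#' `ICC = (BMS - EMS) / (BMS + (k - 1) EMS)` with k = 2, the consistency
#' form that ignores fixed shifts between occasions.  The 95% confidence
#' interval is the exact F-based interval for this model.
#'
#' @param pairs a [paired_measurements()] object (n >= 3).
#' @param conf_level confidence level (default 0.95).
#' @return A list of class `icc_result` with fields `icc`, `ci_lower`,
#'   `ci_upper`, `model`, `bms`, `ems`, `n`, `k`.
#' @export
icc_3_1 <- function(pairs, conf_level = 0.95) {
  stopifnot(inherits(pairs, "paired_measurements"))
  n <- nrow(pairs)
  if (n < 3) stop("ICC needs at least 3 subjects", call. = FALSE)
  k <- 2
  d <- data.frame(
    y = c(pairs$m1, pairs$m2),
    subject = factor(rep(pairs$subject_id, 2)),
    occasion = factor(rep(c(1, 2), each = n))
  )
  if (stats::var(d$y) < 1e-24) stop("zero total variance; ICC undefined", call. = FALSE)
  fit <- stats::aov(y ~ subject + occasion, data = d)
  ms <- summary(fit)[[1]][["Mean Sq"]]
  bms <- ms[1]
  ems <- ms[3]
  icc <- (bms - ems) / (bms + (k - 1) * ems)
  alpha <- 1 - conf_level
  if (ems <= 0) {
    ci <- c(icc, icc)
  } else {
    f_obs <- bms / ems
    df1 <- n - 1
    df2 <- (n - 1) * (k - 1)
    fl <- f_obs / stats::qf(1 - alpha / 2, df1, df2)
    fu <- f_obs * stats::qf(1 - alpha / 2, df2, df1)
    ci <- c((fl - 1) / (fl + k - 1), (fu - 1) / (fu + k - 1))
  }
  structure(
    list(icc = icc, ci_lower = ci[1], ci_upper = ci[2],
         model = "ICC(3,1) two-way mixed, consistency",
         bms = bms, ems = ems, n = n, k = k),
    class = "icc_result"
  )
}

#' Within-subject coefficient of variation
#'
#' For duplicate measurements the within-subject variance of subject i is
#' `(m1_i - m2_i)^2 / 2`; the within-person SD is the root mean of these, and
#' the CV is that SD as a percentage of the grand mean of all measurements.
#'
#' @param pairs a [paired_measurements()] object (n >= 2).
#' @return A list of class `cv_result` with fields `cv_percent`,
#'   `within_sd`, `grand_mean`.
#' @export
coefficient_of_variation <- function(pairs) {
  stopifnot(inherits(pairs, "paired_measurements"))
  if (nrow(pairs) < 2) stop("CV needs at least 2 subjects", call. = FALSE)
  within_var <- (pairs$m1 - pairs$m2)^2 / 2
  within_sd <- sqrt(mean(within_var))
  grand_mean <- mean(c(pairs$m1, pairs$m2))
  if (grand_mean <= 0) stop("grand mean must be positive", call. = FALSE)
  structure(
    list(cv_percent = 100 * within_sd / grand_mean,
         within_sd = within_sd, grand_mean = grand_mean),
    class = "cv_result"
  )
}

#' Correlation between repeatability and a clinical covariate
#'
#' Pearson correlation (with two-sided p value) between absolute paired
#' differences and a clinical activity indicator, screening for activity-
#' dependent disagreement.
#'
#' @param abs_diffs absolute paired differences.
#' @param activity numeric or 0/1 indicator vector of the same length.
#' @return A list with `r` and `p`.
#' @export
activity_correlation <- function(abs_diffs, activity) {
  activity <- as.numeric(activity)
  if (length(abs_diffs) != length(activity) || length(abs_diffs) < 3) {
    stop("need equal-length vectors with at least 3 entries", call. = FALSE)
  }
  if (stats::sd(abs_diffs) < 1e-12 || stats::sd(activity) < 1e-12) {
    stop("constant input; correlation undefined", call. = FALSE)
  }
  ct <- stats::cor.test(abs_diffs, activity)
  list(r = unname(ct$estimate), p = ct$p.value)
}

#' Assemble the per-index agreement report
#'
#' Runs [bland_altman()], [icc_3_1()] and [coefficient_of_variation()] for
#' every index and binds the results into one table mirroring the usual
#' repeatability-study layout (n, bias, limits of agreement, p, CR, mean
#' [SD], CR/mean, ICC with 95% CI, CV).
#'
#' @param measurements a named list of [paired_measurements()] objects (names
#'   are index labels), or a single such object.
#' @return A data frame of class `agreement_report`, one row per index.
#' @export
repeatability_report <- function(measurements) {
  if (inherits(measurements, "paired_measurements")) {
    measurements <- stats::setNames(list(measurements),
                                    attr(measurements, "index") %||% "index")
  }
  rows <- lapply(names(measurements), function(nm) {
    pm <- measurements[[nm]]
    ba <- bland_altman(pm)
    icc <- tryCatch(icc_3_1(pm), error = function(e) NULL)
    cv <- tryCatch(coefficient_of_variation(pm), error = function(e) NULL)
    data.frame(
      index = nm, n = ba$n, bias = ba$bias,
      loa_lower = ba$loa_lower, loa_upper = ba$loa_upper,
      p_value = ba$p_value, cr = ba$CR,
      mean = ba$grand_mean, sd = ba$sd_of_means,
      cr_over_mean = ba$cr_over_mean,
      icc = if (is.null(icc)) NA_real_ else icc$icc,
      icc_ci_lower = if (is.null(icc)) NA_real_ else icc$ci_lower,
      icc_ci_upper = if (is.null(icc)) NA_real_ else icc$ci_upper,
      cv_percent = if (is.null(cv)) NA_real_ else cv$cv_percent,
      stringsAsFactors = FALSE
    )
  })
  out <- do.call(rbind, rows) %||% data.frame()
  class(out) <- c("agreement_report", class(out))
  out
}
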