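# Cohort statistics: one-sample summaries per parameter, top-10% absolute
# values, out-of-range percentages against clinical tolerances, and
# unpaired subgroup contrasts.

#' Metric parameter names, in reporting order
#' @export
METRIC_PARAMETERS <- c("pitch", "roll", "yaw", "trans_LR", "trans_AP", "trans_UD")

#' @keywords internal
ROTATION_PARAMETERS <- c("pitch", "roll", "yaw")

#' @keywords internal
TRANSLATION_PARAMETERS <- c("trans_LR", "trans_AP", "trans_UD")

#' One-sample summary of per-patient differences
#'
#' Mean, SEM, top-10% absolute value, 95% confidence interval, and the
#' two-sided one-sample t-test against zero (df = n - 1), as reported for
#' each segment x parameter cell of a planning-difference cohort table.
#'
#' @param values numeric vector of per-patient differences (degrees or mm).
#' @param conf_level confidence level, default 0.95.
#' @return A list of class `stat_result`: `mean`, `sem`, `top10_value`,
#'   `ci_low`, `ci_high`, `t`, `p_value`, `n`, `degenerate` (TRUE when the
#'   sample variance is zero, in which case p is the 0/1 limit).
#' @export
one_sample_summary <- function(values, conf_level = 0.95) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need n >= 2 values", call. = FALSE)
  if (!all(is.finite(values))) stop("values must be finite", call. = FALSE)
  n <- length(values)
  m <- mean(values)
  sem <- stats::sd(values) / sqrt(n)
  degenerate <- sem == 0
  if (degenerate) {
    tstat <- if (m == 0) 0 else sign(m) * Inf
    p <- if (m == 0) 1 else 0
    ci <- c(m, m)
  } else {
    tt <- stats::t.test(values, mu = 0, conf.level = conf_level)
    tstat <- unname(tt$statistic)
    p <- tt$p.value
    ci <- as.numeric(tt$conf.int)
  }
  structure(list(mean = m, sem = sem, top10_value = top10_value(values),
                 ci_low = ci[1], ci_high = ci[2], t = tstat, p_value = p,
                 n = n, degenerate = degenerate),
            class = "stat_result")
}

#' @export
print.stat_result <- function(x, ...) {
  cat(sprintf("mean %.3f (SEM %.3f, n %d), top-10%% %.3f, 95%% CI [%.3f, %.3f], p %s\n",
              x$mean, x$sem, x$n, x$top10_value, x$ci_low, x$ci_high,
              format_p(x$p_value)))
  invisible(x)
}

#' @keywords internal
format_p <- function(p) {
  ifelse(p < 0.001, "<0.001", formatC(p, digits = 3, format = "f"))
}

#' Confidence interval from summary statistics
#'
#' Reconstructs the 95% (or other level) confidence interval
#' `mean +/- t(1 - alpha/2, n - 1) * sem` from a printed mean and SEM —
#' useful for checking published cohort tables.
#'
#' @param mean sample mean.
#' @param sem standard error of the mean (>= 0).
#' @param n sample size (>= 2).
#' @param conf_level confidence level, default 0.95.
#' @return Numeric vector `c(ci_low, ci_high)`.
#' @examples
#' ci_from_summary(-2.85, 0.68, 26)  # c(-4.25, -1.45) at 2 dp
#' @export
ci_from_summary <- function(mean, sem, n, conf_level = 0.95) {
  if (sem < 0) stop("`sem` must be >= 0", call. = FALSE)
  if (n < 2) stop("`n` must be >= 2", call. = FALSE)
  tq <- stats::qt(1 - (1 - conf_level) / 2, df = n - 1)
  c(ci_low = mean - tq * sem, ci_high = mean + tq * sem)
}

#' One-sample t p-value from summary statistics
#'
#' Two-sided p-value of the one-sample t-test reconstructed from a printed
#' mean and SEM with df = n - 1.
#'
#' @inheritParams ci_from_summary
#' @return p-value in `[0, 1]`.
#' @export
p_from_summary <- function(mean, sem, n) {
  if (sem <= 0) stop("`sem` must be > 0", call. = FALSE)
  2 * stats::pt(-abs(mean / sem), df = n - 1)
}

#' Top-10% absolute value
#'
#' The 90th empirical percentile of the absolute differences: 10% of the
#' observations lie above this magnitude. Computed with linear
#' interpolation between order statistics (`stats::quantile()` type 7).
#'
#' @param values numeric vector, n >= 1.
#' @return The top-10% magnitude, same units as `values`.
#' @export
top10_value <- function(values) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("`values` must be non-empty", call. = FALSE)
  unname(stats::quantile(abs(values), probs = 0.9, type = 7))
}

#' Percentage of out-of-range differences
#'
#' Share of observations whose absolute value strictly exceeds the
#' clinical tolerance (a value exactly at the tolerance is in range).
#'
#' @param values numeric vector.
#' @param tolerance clinical tolerance (> 0), same units as `values`.
#' @return Percentage in `[0, 100]`.
#' @export
out_of_range_percent <- function(values, tolerance) {
  values <- as.numeric(values)
  if (length(values) == 0L) stop("`values` must be non-empty", call. = FALSE)
  if (tolerance <= 0) stop("`tolerance` must be > 0", call. = FALSE)
  100 * mean(abs(values) > tolerance)
}

#' Out-of-range tolerance report for a cohort
#'
#' Per segment and parameter, the percentage of patients whose absolute
#' planning difference exceeds the clinical tolerance (defaults: 4 degrees
#' for rotations, 2 mm for translations), plus per-segment summary rows:
#' `mean_rotations` is the arithmetic mean of the three rotation
#' percentages and `mean_translations` of the three translation
#' percentages.
#'
#' @param cohort a cohort table: data.frame with one row per
#'   patient x segment and columns `segment` plus the six metric
#'   parameters (see [METRIC_PARAMETERS]).
#' @param rot_tol rotation tolerance in degrees, default 4.
#' @param trans_tol translation tolerance in mm, default 2.
#' @return A list of class `tolerance_report`: `percent` (data.frame
#'   segment x parameter), `mean_rotations`, `mean_translations` (named
#'   numeric by segment), and the tolerances used.
#' @export
tolerance_report <- function(cohort, rot_tol = 4, trans_tol = 2) {
  check_cohort(cohort)
  segs <- intersect(SEGMENTS, unique(cohort$segment))
  pct <- do.call(rbind, lapply(segs, function(seg) {
    rows <- cohort[cohort$segment == seg, , drop = FALSE]
    vals <- vapply(METRIC_PARAMETERS, function(p) {
      tol <- if (p %in% ROTATION_PARAMETERS) rot_tol else trans_tol
      out_of_range_percent(rows[[p]], tol)
    }, numeric(1))
    data.frame(segment = seg, t(vals), stringsAsFactors = FALSE)
  }))
  mr <- vapply(seq_len(nrow(pct)), function(i)
    mean(as.numeric(pct[i, ROTATION_PARAMETERS])), numeric(1))
  mt <- vapply(seq_len(nrow(pct)), function(i)
    mean(as.numeric(pct[i, TRANSLATION_PARAMETERS])), numeric(1))
  structure(list(percent = pct,
                 mean_rotations = stats::setNames(mr, pct$segment),
                 mean_translations = stats::setNames(mt, pct$segment),
                 rot_tol = rot_tol, trans_tol = trans_tol),
            class = "tolerance_report")
}

#' @export
print.tolerance_report <- function(x, ...) {
  cat(sprintf("<tolerance_report> tolerances: %.4g deg rotations, %.4g mm translations\n",
              x$rot_tol, x$trans_tol))
  df <- x$percent
  df$mean_rotations <- x$mean_rotations[df$segment]
  df$mean_translations <- x$mean_translations[df$segment]
  print(cbind(segment = df$segment,
              round(df[, setdiff(names(df), "segment")], 2)))
  invisible(x)
}

check_cohort <- function(cohort) {
  needed <- c("patient_id", "segment", METRIC_PARAMETERS)
  missing <- setdiff(needed, names(cohort))
  if (length(missing)) {
    stop("cohort table is missing columns: ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  if (nrow(cohort) == 0L) stop("cohort table is empty", call. = FALSE)
  if (anyDuplicated(cohort[, c("patient_id", "segment")])) {
    stop("cohort table must have one row per (patient, segment)", call. = FALSE)
  }
  invisible(cohort)
}

#' Unpaired subgroup contrast
#'
#' Two-sided unpaired t-test of one metric parameter within one segment,
#' comparing patients with a covariate (e.g. SARME, extraction site)
#' against those without. The mean difference is group-with-effect minus
#' group-without. Welch's unequal-variance test is the default; set
#' `welch = FALSE` for the pooled-variance Student test.
#'
#' @param cohort cohort table with the covariate column (logical/0-1).
#' @param covariate covariate column name, e.g. `"sarme"`.
#' @param parameter one of [METRIC_PARAMETERS].
#' @param segment one of [SEGMENTS].
#' @param welch use Welch's test (default `TRUE`).
#' @param conf_level confidence level, default 0.95.
#' @return A list of class `subgroup_result`: `mean_diff`, `ci_low`,
#'   `ci_high`, `t`, `p_value`, `n_group`, `n_rest`, `covariate`,
#'   `parameter`, `segment`, `welch`.
#' @export
subgroup_test <- function(cohort, covariate, parameter, segment,
                          welch = TRUE, conf_level = 0.95) {
  check_cohort(cohort)
  parameter <- match.arg(parameter, METRIC_PARAMETERS)
  segment <- match.arg(segment, SEGMENTS)
  if (!covariate %in% names(cohort)) {
    stop("unknown covariate column '", covariate, "'", call. = FALSE)
  }
  rows <- cohort[cohort$segment == segment, , drop = FALSE]
  flag <- as.logical(rows[[covariate]])
  if (anyNA(flag)) stop("covariate '", covariate, "' has missing values", call. = FALSE)
  x <- rows[[parameter]][flag]
  y <- rows[[parameter]][!flag]
  if (length(x) < 2L || length(y) < 2L) {
    stop(sprintf("covariate '%s': both groups need n >= 2 (got %d with, %d without)",
                 covariate, length(x), length(y)), call. = FALSE)
  }
  tt <- stats::t.test(x, y, var.equal = !welch, conf.level = conf_level)
  structure(list(mean_diff = mean(x) - mean(y),
                 ci_low = tt$conf.int[1], ci_high = tt$conf.int[2],
                 t = unname(tt$statistic), p_value = tt$p.value,
                 n_group = length(x), n_rest = length(y),
                 covariate = covariate, parameter = parameter,
                 segment = segment, welch = welch),
            class = "subgroup_result")
}

#' @export
print.subgroup_result <- function(x, ...) {
  cat(sprintf("%s / %s / %s: mean diff %.3f, 95%% CI [%.3f, %.3f], p %s (%s, n %d vs %d)\n",
              x$covariate, x$segment, x$parameter, x$mean_diff, x$ci_low,
              x$ci_high, format_p(x$p_value),
              if (x$welch) "Welch" else "Student", x$n_group, x$n_rest))
  invisible(x)
}
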