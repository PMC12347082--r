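# Cohort statistics layer: one-sample summaries, top-10% values,
# out-of-range percentages, tolerance reports, and subgroup contrasts.

test_that("one_sample_summary matches the closed-form t-test on random samples", {
  set.seed(77)
  for (rep in 1:10) {
    x <- rnorm(sample(5:40, 1), mean = runif(1, -2, 2), sd = runif(1, 0.5, 3))
    s <- one_sample_summary(x)
    n <- length(x)
    sem <- sd(x) / sqrt(n)
    tstat <- mean(x) / sem
    expect_equal(s$mean, mean(x))
    expect_equal(s$sem, sem)
    expect_equal(s$t, tstat, tolerance = 1e-12)
    expect_equal(s$p_value, 2 * pt(-abs(tstat), n - 1), tolerance = 1e-12)
    tq <- qt(0.975, n - 1)
    expect_equal(c(s$ci_low, s$ci_high),
                 c(mean(x) - tq * sem, mean(x) + tq * sem), tolerance = 1e-12)
    expect_true(s$ci_low <= s$mean && s$mean <= s$ci_high)
  }
})

test_that("symmetric samples give mean 0 and p = 1; degenerate cases are flagged", {
  s <- one_sample_summary(c(-1, 1))
  expect_equal(s$mean, 0)
  expect_equal(s$p_value, 1)

  s <- one_sample_summary(c(2, 2, 2))
  expect_true(s$degenerate)
  expect_equal(s$p_value, 0)
  expect_equal(s$sem, 0)

  s <- one_sample_summary(c(0, 0, 0))
  expect_true(s$degenerate)
  expect_equal(s$p_value, 1)

  expect_error(one_sample_summary(5), "n >= 2")
})

test_that("confidence intervals reconstruct from printed summary statistics", {
  expect_equal(unname(ci_from_summary(5, 0, 26)), c(5, 5))
  # published-cell reconstructions stable under 2-dp rounding
  expect_equal(round(ci_from_summary(-2.85, 0.68, 26)[["ci_low"]], 2), -4.25)
  expect_equal(round(ci_from_summary(1.19, 0.51, 26)[["ci_high"]], 2), 2.24)
  # the t quantile itself cross-checked against the distribution function
  ci <- ci_from_summary(0, 1, 26)
  expect_equal(pt(ci[["ci_high"]], df = 25), 0.975, tolerance = 1e-12)
})

test_that("CI width is monotone in sem and n", {
  w <- function(sem, n) diff(unname(ci_from_summary(0, sem, n)))
  expect_true(w(0.5, 26) < w(1, 26))
  expect_true(w(1, 50) < w(1, 26))
})

test_that("top10_value is the interpolated 90th percentile of absolute values", {
  expect_equal(top10_value(rep(3, 5)), 3)
  expect_equal(top10_value(-4), 4)
  # 26 values: +/- 1..13; |values| has each of 1..13 twice.
  # type-7 interpolation: position 1 + 0.9 * 25 = 23.5 between the sorted
  # 23rd (12) and 24th (12) values
  vals <- c(1:13, -(1:13))
  a <- sort(abs(vals))
  h <- 1 + 0.9 * (length(a) - 1)
  expected <- a[floor(h)] + (h - floor(h)) * (a[ceiling(h)] - a[floor(h)])
  expect_equal(top10_value(vals), expected)
  expect_equal(expected, 12)
  expect_error(top10_value(numeric(0)), "non-empty")
})

test_that("out_of_range_percent counts strict exceedances only", {
  expect_equal(out_of_range_percent(rep(0, 10), 4), 0)
  expect_equal(out_of_range_percent(c(1, 3, 5), 4), 100 / 3)
  expect_equal(out_of_range_percent(c(4, -4, 3.999), 4), 0)  # boundary in range
  expect_equal(out_of_range_percent(c(-5, 5), 4), 100)
  # monotone non-increasing in tolerance
  set.seed(12)
  x <- rnorm(50, sd = 3)
  tols <- c(0.5, 1, 2, 4, 8)
  p <- vapply(tols, function(tl) out_of_range_percent(x, tl), numeric(1))
  expect_true(all(diff(p) <= 0))
})

test_that("tolerance_report summarises per-parameter percentages and row means", {
  set.seed(3)
  vals <- list(
    dental_maxilla = cbind(rnorm(26, 0, 5), rnorm(26, 0, 1), rnorm(26, 0, 2),
                           rnorm(26, 0, 1), rnorm(26, 0, 2), rnorm(26, 0, 2)),
    dental_mandible = matrix(rnorm(26 * 6, 0, 3), 26),
    bony_mandible = matrix(rnorm(26 * 6, 0, 2), 26))
  cohort <- toy_cohort(vals)
  rep_ <- tolerance_report(cohort)
  for (seg in names(vals)) {
    row <- rep_$percent[rep_$percent$segment == seg, ]
    for (j in 1:6) {
      tol <- if (j <= 3) 4 else 2
      expect_equal(row[[METRIC_PARAMETERS[j]]],
                   100 * mean(abs(vals[[seg]][, j]) > tol))
    }
    expect_equal(rep_$mean_rotations[[seg]],
                 mean(as.numeric(row[c("pitch", "roll", "yaw")])))
    expect_equal(rep_$mean_translations[[seg]],
                 mean(as.numeric(row[c("trans_LR", "trans_AP", "trans_UD")])))
  }

  zero <- toy_cohort(list(dental_maxilla = matrix(0, 5, 6)))
  rep0 <- tolerance_report(zero)
  expect_equal(unname(unlist(rep0$percent[, METRIC_PARAMETERS])), rep(0, 6))
})

test_that("subgroup_test matches an independent Welch-Satterthwaite computation", {
  cohort <- toy_cohort(list(dental_maxilla = matrix(
    c(-4.2, -1.1, -3.3, -5.0, -0.4, -2.2, -1.8, -2.9), ncol = 6, nrow = 8)))
  cohort$sarme <- c(TRUE, TRUE, TRUE, FALSE, FALSE, FALSE, FALSE, TRUE)
  r <- subgroup_test(cohort, "sarme", "pitch", "dental_maxilla")

  x <- cohort$pitch[cohort$sarme]; y <- cohort$pitch[!cohort$sarme]
  se <- sqrt(var(x) / length(x) + var(y) / length(y))
  df <- se^4 / ((var(x) / length(x))^2 / (length(x) - 1) +
                (var(y) / length(y))^2 / (length(y) - 1))
  tstat <- (mean(x) - mean(y)) / se
  expect_equal(r$mean_diff, mean(x) - mean(y))
  expect_equal(r$t, tstat, tolerance = 1e-12)
  expect_equal(r$p_value, 2 * pt(-abs(tstat), df), tolerance = 1e-12)
  tq <- qt(0.975, df)
  expect_equal(c(r$ci_low, r$ci_high),
               c(r$mean_diff - tq * se, r$mean_diff + tq * se),
               tolerance = 1e-12)
})

test_that("identical groups give zero difference and p = 1", {
  m <- matrix(rep(c(1, 2, 3, 4), 6), ncol = 6)
  cohort <- toy_cohort(list(bony_mandible = rbind(m, m)))
  cohort$sarme <- rep(c(TRUE, FALSE), each = 4)
  r <- subgroup_test(cohort, "sarme", "yaw", "bony_mandible")
  expect_equal(r$mean_diff, 0)
  expect_equal(r$p_value, 1)
})

test_that("subgroup CIs cover a known shift at the nominal rate", {
  set.seed(2024)
  delta <- 1.5
  hits <- 0L
  reps <- 400L
  for (i in seq_len(reps)) {
    x <- rnorm(40, delta); y <- rnorm(40, 0)
    cohort <- toy_cohort(list(dental_mandible = matrix(c(x, y), ncol = 6,
                                                       nrow = 80)))
    cohort$sarme <- rep(c(TRUE, FALSE), each = 40)
    r <- subgroup_test(cohort, "sarme", "pitch", "dental_mandible")
    if (r$ci_low <= delta && delta <= r$ci_high) hits <- hits + 1L
  }
  # binomial(400, .95) 3-sigma band
  expect_gt(hits / reps, 0.95 - 3 * sqrt(0.95 * 0.05 / reps))
  expect_lt(hits / reps, 0.95 + 3 * sqrt(0.95 * 0.05 / reps))
})

test_that("subgroup_test enforces group sizes and known covariates", {
  cohort <- toy_cohort(list(dental_maxilla = matrix(rnorm(30), 5, 6)))
  cohort$sarme <- c(TRUE, rep(FALSE, 4))
  expect_error(subgroup_test(cohort, "sarme", "pitch", "dental_maxilla"),
               "n >= 2")
  expect_error(subgroup_test(cohort, "unknown_flag", "pitch", "dental_maxilla"),
               "covariate")
})
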