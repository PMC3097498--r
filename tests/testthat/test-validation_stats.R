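test_that("calibration fit recovers exact generator parameters", {
  conc <- c(0.5, 1, 2, 3, 4, 5)
  fit <- fit_calibration(conc, 601211 * conc + 41127)
  expect_equal(fit$slope, 601211, tolerance = 1e-9)
  expect_equal(fit$intercept, 41127, tolerance = 1e-9)
  expect_equal(fit$r_squared, 1, tolerance = 1e-12)
  expect_equal(fit$range_low, 0.5)
  expect_equal(fit$range_high, 5)
  expect_equal(fit$n_points, 6L)
})

test_that("degenerate calibrations behave", {
  expect_equal(fit_calibration(1:5, rep(10, 5))$slope, 0, tolerance = 1e-12)
  expect_error(fit_calibration(c(1, 1, 1), c(1, 2, 3)), "distinct")
  expect_error(fit_calibration(1:3, 1:4), "length")
})

test_that("OLS matches the closed-form normal equations on random data", {
  set.seed(31)
  for (rep in 1:50) {
    x <- runif(8, 0.5, 5)
    y <- 5e5 * x + 4e4 + rnorm(8, sd = 1e4)
    fit <- fit_calibration(x, y)
    n <- length(x)
    slope <- (sum(x * y) - n * mean(x) * mean(y)) /
      (sum(x^2) - n * mean(x)^2)
    expect_equal(fit$slope, slope, tolerance = 1e-9)
    expect_equal(fit$intercept, mean(y) - slope * mean(x), tolerance = 1e-9)
  }
})

test_that("%RSD uses the sample standard deviation and matches print", {
  # published day-1 values at the 80 mg and 100 mg levels
  expect_printed(percent_rsd(c(78.34, 79.43, 81.33)), 1.89)
  expect_printed(percent_rsd(c(101.69, 99.68, 100.72)), 0.99)
  # population sd would give ~1.55 at 80 mg -- must not match
  expect_gt(percent_rsd(c(78.34, 79.43, 81.33)), 1.8)
  expect_equal(percent_rsd(rep(3.2, 5)), 0)
  expect_error(percent_rsd(7), "two values")
  expect_error(percent_rsd(c(-1, 1)), "zero mean")
  # scale invariance
  set.seed(5)
  x <- rlnorm(20, 3, 0.2)
  for (c in c(0.01, 1, 250)) {
    expect_equal(percent_rsd(c * x), percent_rsd(x), tolerance = 1e-12)
  }
})

test_that("recovery ANOVA reproduces all nine published mean squares", {
  printed <- list(
    "80" = c(wms = 1.64, bms = 1.72, f = 1.05),
    "100" = c(wms = 2.79, bms = 6.79, f = 2.43),
    "120" = c(wms = 2.34, bms = 3.82, f = 1.63))
  printed_rsd <- list("80" = c(1.89, 1.15, 1.64),
                      "100" = c(0.99, 1.67, 2.10),
                      "120" = c(0.96, 1.25, 1.53))
  printed_means <- list("80" = c(79.70, 80.14, 81.18),
                        "100" = c(100.69, 99.21, 102.22),
                        "120" = c(119.36, 119.16, 121.21))
  for (lvl in names(recovery_values())) {
    p <- anova_precision(recovery_values()[[lvl]],
                         spike_level = as.numeric(lvl))
    expect_printed(p$wms, printed[[lvl]][["wms"]])
    expect_printed(p$bms, printed[[lvl]][["bms"]])
    expect_printed(p$f_statistic, printed[[lvl]][["f"]])
    for (d in 1:3) {
      expect_printed(p$day_rsd_percent[d], printed_rsd[[lvl]][d])
      expect_printed(p$day_means[d], printed_means[[lvl]][d])
    }
    # independent oracle: stats::aov one-way layout on the same panel
    long <- data.frame(y = as.numeric(p$values),
                       day = factor(rep(1:3, times = 3)))
    tab <- summary(stats::aov(y ~ day, data = long))[[1]]
    expect_equal(p$bms, tab["day", "Mean Sq"], tolerance = 1e-10)
    expect_equal(p$wms, tab["Residuals", "Mean Sq"], tolerance = 1e-10)
    expect_equal(p$day_means, rowMeans(p$values), ignore_attr = TRUE)
  }
})

test_that("ANOVA degenerate inputs and decomposition invariant", {
  same <- matrix(5, 3, 3)
  p <- anova_precision(same)
  expect_equal(p$bms, 0)
  expect_equal(p$wms, 0)
  expect_true(is.na(p$f_statistic))
  expect_error(anova_precision(matrix(1:3, 1, 3)), "at least 2 days")
  expect_error(anova_precision(matrix(c(1, 2, NA, 4), 2, 2)), "complete")
  set.seed(77)
  for (rep in 1:100) {
    m <- matrix(rnorm(12, 100, 3), nrow = 3)  # 3 days x 4 replicates
    p <- anova_precision(m)
    total <- sum((m - mean(m))^2)
    expect_equal(p$bms * p$df_between + p$wms * p$df_within, total,
                 tolerance = 1e-10)
  }
})

test_that("critical F values come from the quantile function", {
  expect_equal(round(f_critical(2, 6, 0.05), 2), 5.14)
  # quantile/CDF round trip
  q <- f_critical(3, 9, 0.01)
  expect_equal(1 - pf(q, 3, 9), 0.01, tolerance = 1e-12)
  # F(1, m) is the square of the two-sided t critical value
  expect_equal(f_critical(1, 10, 0.05), qt(0.975, 10)^2, tolerance = 1e-12)
  expect_error(f_critical(0, 6), ">= 1")
  expect_error(f_critical(2, 6, 1.2), "alpha")
})

test_that("precision verdicts: published panels pass, shifted panel fails", {
  for (lvl in names(recovery_values())) {
    p <- anova_precision(recovery_values()[[lvl]])
    v <- precision_verdict(p)
    expect_true(v$pass)
    expect_lt(v$f_statistic, v$f_critical)
    expect_match(v$narrative, "intermediate precision acceptable")
  }
  # day means ten within-day sd apart must be flagged
  shifted <- simulate_recovery_panel(100, between_day_sd = 10,
                                     within_day_sd = 1, seed = 123)
  expect_false(precision_verdict(anova_precision(shifted))$pass)
  # undefined F propagates as indeterminate
  v0 <- precision_verdict(anova_precision(matrix(5, 3, 3)))
  expect_true(is.na(v0$pass))
  expect_match(v0$narrative, "indeterminate")
})
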