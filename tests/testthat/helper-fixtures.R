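# Shared fixtures: the published alkali-degradation experiment and the
# accuracy/precision recovery panels, built in code so every test file
# can use them without touching the filesystem.

alkali_factors <- function() {
  list(fd_factor("naoh", 0.1, 1.0, "N"),
       fd_factor("time", 15, 30, "min"),
       fd_factor("power", 420, 700, "W"))
}

alkali_responses <- function() c(0, 0, 2, 8, 17, 21, 28, 33)

alkali_design <- function() {
  attach_responses(build_full_factorial(alkali_factors()),
                   alkali_responses())
}

# Saturated coefficients of the alkali experiment, exact rationals
# (contrast totals divided by 8) in term order 1, X1, X2, X3, X1X2,
# X1X3, X2X3, X1X2X3.
alkali_beta_exact <- function() {
  c(109, 15, 33, 89, 7, 3, 13, -5) / 8
}

# The published reduced equation entered at its printed (2 dp) precision.
reduced_printed_model <- function() {
  factorial_model(c("1", "X2", "X3", "X2X3"),
                  c(13.62, 4.12, 11.12, 1.62),
                  alkali_factors())
}

# Recovery panels, rows = days, columns = replicates (mg found).
recovery_values <- function() {
  list(
    "80" = rbind(day1 = c(78.34, 79.43, 81.33),
                 day2 = c(79.24, 81.09, 80.11),
                 day3 = c(80.39, 80.43, 82.72)),
    "100" = rbind(day1 = c(101.69, 99.68, 100.72),
                  day2 = c(98.75, 97.83, 101.06),
                  day3 = c(99.85, 102.79, 104.03)),
    "120" = rbind(day1 = c(118.11, 120.36, 119.62),
                  day2 = c(120.16, 119.88, 117.44),
                  day3 = c(119.86, 120.43, 123.34)))
}

# Published two-decimal statistics were truncated, not rounded, and the
# printed F values derive from the truncated mean squares; one display
# ulp of absolute slack covers both conventions.
expect_printed <- function(x, printed) {
  expect_lt(abs(x - printed), 0.0101)
}

# Independent coefficient oracle: dense least squares through stats::lm
# on the full interaction formula, mapped back to "X..." term labels.
lm_oracle_coefs <- function(runs, y) {
  k <- ncol(runs)
  df <- as.data.frame(runs * 1.0)
  names(df) <- paste0("x", seq_len(k))
  df$y <- y
  fml <- stats::as.formula(paste("y ~", paste(names(df)[seq_len(k)],
                                              collapse = " * ")))
  co <- stats::coef(stats::lm(fml, data = df))
  labs <- vapply(names(co), function(nm) {
    if (nm == "(Intercept)") return("1")
    idx <- sort(as.integer(sub("x", "", strsplit(nm, ":", fixed = TRUE)[[1]])))
    paste0("X", idx, collapse = "")
  }, character(1))
  stats::setNames(as.numeric(co), labs)
}
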