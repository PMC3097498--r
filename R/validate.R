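#' Fit a calibration line by ordinary least squares
#'
#' Regresses peak area on concentration and reports slope, intercept and
#' the coefficient of determination (squared Pearson correlation), the
#' standard linearity summary for a chromatographic calibration.
#'
#' @param concentrations Numeric vector (e.g. micrograms per mL); at
#'   least three distinct values.
#' @param areas Numeric vector of peak areas, same length.
#' @return A `calibration_fit`: list with `slope`, `intercept`,
#'   `r_squared`, `range_low`, `range_high`, `n_points`.
#' @export
fit_calibration <- function(concentrations, areas) {
  concentrations <- as.numeric(concentrations)
  areas <- as.numeric(areas)
  if (length(concentrations) != length(areas)) {
    stop("concentrations and areas differ in length", call. = FALSE)
  }
  if (length(unique(concentrations)) < 3L) {
    stop("need at least three distinct concentrations", call. = FALSE)
  }
  fit <- stats::lm(areas ~ concentrations)
  co <- stats::coef(fit)
  r2 <- if (stats::var(areas) == 0) 1 else stats::cor(concentrations, areas)^2
  structure(
    list(slope = unname(co[2L]), intercept = unname(co[1L]),
         r_squared = r2,
         range_low = min(concentrations), range_high = max(concentrations),
         n_points = length(concentrations)),
    class = "calibration_fit"
  )
}

#' @export
print.calibration_fit <- function(x, ...) {
  cat(sprintf("calibration: area = %.6g * conc %+.6g  (r^2 = %.5f, n = %d, range %g-%g)\n",
              x$slope, x$intercept, x$r_squared, x$n_points,
              x$range_low, x$range_high))
  invisible(x)
}

#' Percent relative standard deviation
#'
#' `100 * sd(x) / mean(x)` with the sample (n-1) standard deviation --
#' the precision measure reported for replicate recoveries.
#'
#' @param values Numeric vector, length >= 2, nonzero mean.
#' @return %RSD as a numeric scalar.
#' @export
percent_rsd <- function(values) {
  values <- as.numeric(values)
  if (length(values) < 2L) stop("need at least two values", call. = FALSE)
  m <- mean(values)
  if (m == 0) stop("%RSD undefined for zero mean", call. = FALSE)
  100 * stats::sd(values) / m
}

#' One-way ANOVA of a recovery panel (within/between day)
#'
#' Summarises a balanced days x replicates matrix of amount-found values
#' at one spike level. Groups are days, so the between mean square (BMS)
#' captures inter-day variability and the within mean square (WMS)
#' intra-day variability:
#' \deqn{BMS = r \sum_d (\bar y_d - \bar y)^2 / (d - 1), \quad
#'       WMS = \sum_d \sum_r (y_{dr} - \bar y_d)^2 / (d (r - 1))}
#' and `F = BMS / WMS`. When `WMS` is exactly zero the F statistic is
#' reported as `NA` (undefined), not infinity.
#'
#' @param values Numeric matrix, rows = days (>= 2), columns =
#'   replicates (>= 2), balanced.
#' @param spike_level Optional amount added (mg), carried for reporting.
#' @return A `recovery_panel`: list with `spike_level`, `values`,
#'   `day_means`, `day_rsd_percent`, `grand_mean`,
#'   `mean_recovery_percent` (if `spike_level` given), `wms`, `bms`,
#'   `f_statistic`, `df_between`, `df_within`.
#' @export
anova_precision <- function(values, spike_level = NULL) {
  values <- as.matrix(values)
  if (!is.numeric(values) || anyNA(values)) {
    stop("panel must be a complete numeric matrix", call. = FALSE)
  }
  d <- nrow(values)
  r <- ncol(values)
  if (d < 2L || r < 2L) {
    stop("need at least 2 days and 2 replicates per day", call. = FALSE)
  }
  day_means <- rowMeans(values)
  grand <- mean(values)
  bss <- r * sum((day_means - grand)^2)
  wss <- sum((values - day_means)^2)   # day_means recycles down columns
  bms <- bss / (d - 1L)
  wms <- wss / (d * (r - 1L))
  structure(
    list(spike_level = spike_level, values = values,
         day_means = day_means,
         day_rsd_percent = apply(values, 1L, percent_rsd),
         grand_mean = grand,
         mean_recovery_percent = if (!is.null(spike_level)) {
           100 * grand / spike_level
         },
         wms = wms, bms = bms,
         f_statistic = if (wms > 0) bms / wms else NA_real_,
         df_between = d - 1L, df_within = d * (r - 1L)),
    class = "recovery_panel"
  )
}

#' @export
print.recovery_panel <- function(x, ...) {
  lvl <- if (is.null(x$spike_level)) "" else sprintf(" (%g mg added)",
                                                     x$spike_level)
  cat(sprintf("recovery panel%s: %d days x %d replicates\n",
              lvl, nrow(x$values), ncol(x$values)))
  cat(sprintf("  day means: %s\n", paste(sprintf("%.2f", x$day_means),
                                         collapse = ", ")))
  cat(sprintf("  day %%RSD:  %s\n", paste(sprintf("%.2f", x$day_rsd_percent),
                                          collapse = ", ")))
  cat(sprintf("  WMS = %.4f, BMS = %.4f, F(%d,%d) = %s\n",
              x$wms, x$bms, x$df_between, x$df_within,
              if (is.na(x$f_statistic)) "undefined"
              else sprintf("%.4f", x$f_statistic)))
  invisible(x)
}

#' Upper critical value of the F distribution
#'
#' The upper-alpha quantile, i.e. the tabulated F value against which an
#' observed ANOVA F statistic is compared.
#'
#' @param df1,df2 Numerator and denominator degrees of freedom (>= 1).
#' @param alpha Tail probability in (0, 1); default 0.05.
#' @return Numeric scalar.
#' @examples
#' f_critical(2, 6)  # 5.143...
#' @export
f_critical <- function(df1, df2, alpha = 0.05) {
  if (df1 < 1 || df2 < 1) stop("degrees of freedom must be >= 1",
                               call. = FALSE)
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)", call. = FALSE)
  stats::qf(1 - alpha, df1, df2)
}

#' Intermediate-precision verdict for a recovery panel
#'
#' Compares the panel's between/within F statistic with the critical
#' value `f_critical(d - 1, d (r - 1), alpha)`. A pass (F below the
#' critical value) means day-to-day variability is not distinguishable
#' from replicate scatter -- the intermediate-precision requirement.
#'
#' @param panel A `recovery_panel` from [anova_precision()].
#' @param alpha Significance level (default 0.05).
#' @return List with `pass` (`TRUE`/`FALSE`/`NA` when F is undefined),
#'   `f_statistic`, `f_critical`, `alpha`, `narrative`.
#' @export
precision_verdict <- function(panel, alpha = 0.05) {
  stopifnot(inherits(panel, "recovery_panel"))
  fc <- f_critical(panel$df_between, panel$df_within, alpha)
  f <- panel$f_statistic
  if (is.na(f)) {
    return(list(pass = NA, f_statistic = f, f_critical = fc, alpha = alpha,
                narrative = "F undefined (zero within-day mean square); verdict indeterminate"))
  }
  pass <- f < fc
  list(
    pass = pass, f_statistic = f, f_critical = fc, alpha = alpha,
    narrative = sprintf(
      "F(%d,%d) = %.2f %s critical %.2f at alpha = %g: %s",
      panel$df_between, panel$df_within, f,
      if (pass) "<" else ">=", fc, alpha,
      if (pass) {
        "no significant inter-day effect; intermediate precision acceptable"
      } else {
        "significant inter-day variability detected"
      }))
}
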