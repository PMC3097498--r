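## File dialects (all plain text):
##   design CSV:      run,<factor1>,...,response   (factor columns in
##                    actual units, or -1/+1 with coded = TRUE; response
##                    column optional)
##   factor config:   JSON array of {name, low, high, units}
##   model JSON:      {factors: [...], terms: ["1","X2",...],
##                    coefficients: [...]}
##   recovery CSV:    level_mg,day,replicate,amount_found_mg
##   calibration CSV: concentration_ug_ml,peak_area

read_numeric_csv <- function(path, required) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = "character", check.names = FALSE)
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop(sprintf("%s: missing required column(s): %s",
                 basename(path), paste(missing, collapse = ", ")),
         call. = FALSE)
  }
  for (col in names(df)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    bad <- which(is.na(v) & nzchar(trimws(df[[col]])))
    if (length(bad)) {
      stop(sprintf("%s: non-numeric value '%s' in column '%s', row %d",
                   basename(path), df[[col]][bad[1L]], col, bad[1L]),
           call. = FALSE)
    }
    df[[col]] <- v
  }
  df
}

#' Read a factor configuration file
#'
#' @param path JSON file holding an array of objects with fields
#'   `name`, `low`, `high` and optional `units`.
#' @return List of [fd_factor] objects.
#' @export
read_factor_config <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  if (is.data.frame(raw)) raw <- split(raw, seq_len(nrow(raw)))
  unname(lapply(raw, function(f) {
    fd_factor(f$name, f$low, f$high, if (is.null(f$units)) "" else f$units)
  }))
}

#' Write a factor configuration file
#'
#' @param factors List of [fd_factor] objects.
#' @param path Output JSON path.
#' @export
write_factor_config <- function(factors, path) {
  jsonlite::write_json(
    lapply(factors, function(f) f[c("name", "low", "high", "units")]),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a factorial design (and responses) from CSV
#'
#' The file must carry a `run` column, one column per configured factor
#' (actual units unless `coded = TRUE`) and optionally a `response`
#' column. Runs in any order are accepted and permuted to standard
#' (Yates) order; the run set must form a complete 2^k design.
#'
#' @param path CSV path.
#' @param factors List of [fd_factor] (the column contract).
#' @param coded If `TRUE`, factor columns already hold -1/+1.
#' @return A `factorial_design` (with responses if the column exists).
#' @export
read_design_csv <- function(path, factors, coded = FALSE) {
  nms <- vapply(factors, `[[`, character(1), "name")
  df <- read_numeric_csv(path, required = c("run", nms))
  runs <- as.matrix(df[, nms, drop = FALSE])
  if (!coded) {
    for (j in seq_along(factors)) {
      runs[, j] <- code_value(runs[, j], factors[[j]])
    }
    # midpoint/half-range arithmetic need not be exact in binary floating
    # point; snap values numerically at the +/-1 corners
    near <- abs(abs(runs) - 1) < 1e-9
    runs[near] <- sign(runs[near])
  }
  if (!all(runs %in% c(-1, 1))) {
    stop(sprintf(
      "%s: factor levels do not match the configured low/high values%s",
      basename(path),
      if (coded) "" else " (after coding; expected only the two levels)"),
      call. = FALSE)
  }
  std <- standardize_runs(runs, df$response)
  design <- build_full_factorial(factors)
  stopifnot(identical(unname(design$runs * 1.0), unname(std$runs * 1.0)))
  if (!is.null(std$responses)) design <- attach_responses(design,
                                                          std$responses)
  design
}

#' Write a factorial design to CSV
#'
#' @param design A `factorial_design`.
#' @param path Output path.
#' @param actual Write factor columns in actual units (default) or
#'   coded -1/+1.
#' @export
write_design_csv <- function(design, path, actual = TRUE) {
  stopifnot(is_factorial_design(design))
  m <- if (actual) actual_runs(design) else design$runs
  df <- data.frame(run = seq_len(nrow(m)), m, check.names = FALSE)
  if (!is.null(design$responses)) df$response <- design$responses
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Write a factorial model to JSON
#'
#' The file is round-trippable through [read_model_json()] at full
#' double precision.
#'
#' @param model A `factorial_model`.
#' @param path Output path.
#' @export
write_model_json <- function(model, path) {
  stopifnot(is_factorial_model(model))
  jsonlite::write_json(
    list(factors = lapply(model$factors,
                          function(f) f[c("name", "low", "high", "units")]),
         terms = names(model$coefficients),
         coefficients = as.numeric(model$coefficients)),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Read a factorial model from JSON
#'
#' @param path Path written by [write_model_json()] (or hand-authored
#'   in the same schema).
#' @return A `factorial_model`.
#' @export
read_model_json <- function(path) {
  if (!file.exists(path)) stop(sprintf("file not found: %s", path),
                               call. = FALSE)
  raw <- jsonlite::fromJSON(path, simplifyDataFrame = TRUE)
  factors <- raw$factors
  if (is.data.frame(factors)) factors <- split(factors, seq_len(nrow(factors)))
  factors <- unname(lapply(factors, function(f) {
    fd_factor(f$name, f$low, f$high, if (is.null(f$units)) "" else f$units)
  }))
  factorial_model(as.character(raw$terms), as.numeric(raw$coefficients),
                  factors)
}

#' Read recovery panels from a long-format CSV
#'
#' Expects columns `level_mg, day, replicate, amount_found_mg`; one
#' balanced days x replicates panel is assembled per spike level and
#' summarised with [anova_precision()].
#'
#' @param path CSV path.
#' @return Named list of `recovery_panel` objects, one per level, in
#'   ascending level order.
#' @export
read_recovery_csv <- function(path) {
  df <- read_numeric_csv(path, required = c("level_mg", "day", "replicate",
                                            "amount_found_mg"))
  levels <- sort(unique(df$level_mg))
  panels <- lapply(levels, function(lvl) {
    sub <- df[df$level_mg == lvl, ]
    days <- sort(unique(sub$day))
    reps <- sort(unique(sub$replicate))
    m <- matrix(NA_real_, nrow = length(days), ncol = length(reps),
                dimnames = list(paste0("day", days), paste0("rep", reps)))
    for (i in seq_len(nrow(sub))) {
      m[match(sub$day[i], days), match(sub$replicate[i], reps)] <-
        sub$amount_found_mg[i]
    }
    if (anyNA(m)) {
      stop(sprintf("%s: level %g is not a complete balanced panel",
                   basename(path), lvl), call. = FALSE)
    }
    anova_precision(m, spike_level = lvl)
  })
  stats::setNames(panels, paste0(levels, "mg"))
}

#' Read a calibration CSV
#'
#' @param path CSV with columns `concentration_ug_ml, peak_area`.
#' @return Data frame with columns `concentration`, `area`.
#' @export
read_calibration_csv <- function(path) {
  df <- read_numeric_csv(path, required = c("concentration_ug_ml",
                                            "peak_area"))
  data.frame(concentration = df$concentration_ug_ml, area = df$peak_area)
}

## ---- report rendering ----------------------------------------------------

fmt2 <- function(x) format(round(x, 2), trim = TRUE, nsmall = 2)

#' Render a model-fitting report
#'
#' Human-readable summary of a saturated fit and its effect screen.
#' Displayed numbers are rounded half-to-even at two decimals; use the
#' JSON/CSV outputs for full precision.
#'
#' @param model A `factorial_model`.
#' @param screen An `effect_screen` (optional).
#' @return Character vector of report lines.
#' @export
render_fit_report <- function(model, screen = NULL) {
  lines <- c(
    "== factorial fit ==",
    sprintf("factors: %s",
            paste(vapply(model$factors, function(f) {
              sprintf("%s [%g..%g %s]", f$name, f$low, f$high, f$units)
            }, character(1)), collapse = "; ")),
    model_equation(model))
  if (!is.null(screen)) {
    lines <- c(lines, "", "== effect screen (pooled-error F test) ==",
               sprintf("pooled terms: %s (error MS %s on %d df)",
                       paste(screen$term[screen$pooled], collapse = ", "),
                       fmt2(attr(screen, "pooled_error_ms")),
                       attr(screen, "pool_df")),
               sprintf("critical F(1,%d) at alpha %g: %s",
                       attr(screen, "pool_df"), attr(screen, "alpha"),
                       fmt2(attr(screen, "f_critical"))))
    tested <- screen[!screen$pooled, ]
    tested <- tested[order(-tested$f_statistic), ]
    lines <- c(lines, vapply(seq_len(nrow(tested)), function(i) {
      sprintf("  %-8s effect %7s  SS %8s  F %8s  %s",
              tested$term[i], fmt2(tested$effect[i]), fmt2(tested$sum_sq[i]),
              fmt2(tested$f_statistic[i]),
              if (tested$significant[i]) "significant" else "ns")
    }, character(1)))
  }
  lines
}

#' Render a method-validation report
#'
#' @param calibration A `calibration_fit`, or `NULL`.
#' @param panels List of `recovery_panel` objects, or `NULL`.
#' @param alpha Significance level for the precision F test.
#' @return Character vector of report lines.
#' @export
render_validation_report <- function(calibration = NULL, panels = NULL,
                                     alpha = 0.05) {
  lines <- "== method validation =="
  if (!is.null(calibration)) {
    lines <- c(lines, sprintf(
      "calibration: area = %.0f * conc + %.0f over %g-%g (r^2 = %.4f, n = %d)",
      calibration$slope, calibration$intercept,
      calibration$range_low, calibration$range_high,
      calibration$r_squared, calibration$n_points))
  }
  for (p in panels) {
    v <- precision_verdict(p, alpha)
    lines <- c(lines,
               "",
               sprintf("level %s mg: day means %s; day %%RSD %s",
                       format(p$spike_level),
                       paste(fmt2(p$day_means), collapse = " / "),
                       paste(fmt2(p$day_rsd_percent), collapse = " / ")),
               if (!is.null(p$mean_recovery_percent)) {
                 sprintf("  mean recovery %s%%", fmt2(p$mean_recovery_percent))
               },
               sprintf("  WMS %s  BMS %s  %s", fmt2(p$wms), fmt2(p$bms),
                       v$narrative))
  }
  lines
}

#' Render an optimization report
#'
#' Includes a solver note: the closed-form inversion divides by the sum
#' of the coefficients of all terms containing the solved factor,
#' evaluated at the fixed coordinates -- the correct linear-in-one-
#' coordinate rearrangement of the fitted polynomial.
#'
#' @param rec Output of [recommend_conditions()].
#' @return Character vector of report lines.
#' @export
render_optimize_report <- function(rec) {
  c("== recommended operating conditions ==",
    sprintf("solved factor: %s%s", rec$solved_factor,
            if (rec$in_design_space) "" else "  [EXTRAPOLATED]"),
    vapply(seq_len(nrow(rec$settings)), function(i) {
      s <- rec$settings[i, ]
      sprintf("  %-12s coded %7s  actual %.4g %s",
              s$factor, fmt2(s$coded), s$actual, s$units)
    }, character(1)),
    sprintf("predicted degradation: %s%%", fmt2(rec$predicted_y)),
    "note: solved coordinate = (target - value of terms without the factor)",
    "      / (sum of coefficients of terms containing it, at the fixed",
    "      coordinates); verified by back-substitution to 1e-9.")
}
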