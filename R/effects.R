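#' Construct a factorial regression model
#'
#' Low-level constructor pairing term labels with coefficients. Most
#' users obtain models from [estimate_coefficients()] or
#' [reduce_model()]; the constructor exists so a published equation can
#' be entered directly.
#'
#' @param terms Character vector of term labels (`"1"`, `"X2"`,
#'   `"X2X3"`, ...) or a list of integer index vectors. The intercept
#'   must be present.
#' @param coefficients Numeric vector aligned with `terms`.
#' @param factors List of [fd_factor] objects the `Xi` indices refer to.
#' @return An object of class `factorial_model`.
#' @examples
#' # A reduced two-factor-plus-interaction equation:
#' fs <- list(fd_factor("naoh", 0.1, 1, "N"),
#'            fd_factor("time", 15, 30, "min"),
#'            fd_factor("power", 420, 700, "W"))
#' factorial_model(c("1", "X2", "X3", "X2X3"),
#'                 c(13.62, 4.12, 11.12, 1.62), fs)
#' @export
factorial_model <- function(terms, coefficients, factors) {
  if (is.character(terms)) terms <- lapply(terms, parse_term_label)
  stopifnot(is.list(terms), is.numeric(coefficients))
  if (is_fd_factor(factors)) factors <- list(factors)
  stopifnot(all(vapply(factors, is_fd_factor, logical(1))))
  if (length(terms) != length(coefficients)) {
    stop("terms and coefficients differ in length", call. = FALSE)
  }
  labels <- term_labels(terms)
  if (anyDuplicated(labels)) stop("duplicate model terms", call. = FALSE)
  if (!"1" %in% labels) stop("model must contain an intercept", call. = FALSE)
  k <- length(factors)
  bad <- vapply(terms, function(t) length(t) && max(t) > k, logical(1))
  if (any(bad)) {
    stop("term references a factor index beyond the factor list",
         call. = FALSE)
  }
  structure(
    list(terms = terms, coefficients = stats::setNames(as.numeric(coefficients),
                                                       labels),
         factors = factors),
    class = "factorial_model"
  )
}

is_factorial_model <- function(x) inherits(x, "factorial_model")

#' Estimate all 2^k coefficients of a saturated factorial model
#'
#' For a full two-level design with +/-1 coding, the least-squares
#' coefficient of any term equals the orthogonal-contrast average
#' `sum(column * y) / n`, where `column` is the elementwise product of
#' the coded factor columns in the term and `n = 2^k`. The intercept is
#' the response mean. Because the model is saturated (one coefficient
#' per run) the fit reproduces every observation exactly.
#'
#' @param design A `factorial_design` with responses attached.
#' @return A `factorial_model` with all `2^k` terms.
#' @seealso [yates_algorithm()] for the tabular route to the same
#'   contrasts; [screen_effects()] for significance screening.
#' @export
estimate_coefficients <- function(design) {
  stopifnot(is_factorial_design(design))
  if (is.null(design$responses)) {
    stop("design has no responses; use attach_responses()", call. = FALSE)
  }
  if (!all(design$runs %in% c(-1, 1))) {
    stop("design runs must be coded -1/+1", call. = FALSE)
  }
  k <- design_k(design)
  terms <- all_terms(k)
  n <- nrow(design$runs)
  X <- design_model_matrix(design$runs, terms)
  beta <- as.numeric(crossprod(X, design$responses)) / n
  factorial_model(terms, beta, design$factors)
}

#' Yates tabular algorithm for factorial contrasts
#'
#' The pencil-and-paper algorithm: given the `2^k` responses in standard
#' order, perform `k` passes, each replacing the vector by the pairwise
#' sums of adjacent entries followed by the pairwise differences
#' (second minus first). The final vector holds the contrast totals,
#' one per model term. Dividing by `2^k` gives coefficients, by
#' `2^(k-1)` gives effects, and `contrast^2 / 2^k` gives each term's
#' sum of squares.
#'
#' @param responses Numeric vector of length `2^k` in standard order.
#' @return Named numeric vector of contrast totals. Names follow the
#'   algorithm's natural (binary) term order: `1, X1, X2, X1X2, X3, ...`
#' @export
yates_algorithm <- function(responses) {
  responses <- as.numeric(responses)
  n <- length(responses)
  k <- as.integer(round(log2(n)))
  if (n < 2L || 2L^k != n) {
    stop("response length must be a power of two (>= 2)", call. = FALSE)
  }
  v <- responses
  for (pass in seq_len(k)) {
    odd <- v[seq(1L, n, by = 2L)]
    even <- v[seq(2L, n, by = 2L)]
    v <- c(even + odd, even - odd)
  }
  # row i (0-based) of the output corresponds to the term whose factor
  # set is the binary expansion of i, factor 1 = least significant bit
  labs <- vapply(seq_len(n) - 1L, function(i) {
    term_label(which(bitwAnd(i, 2L^(seq_len(k) - 1L)) > 0L))
  }, character(1))
  stats::setNames(v, labs)
}

#' Screen factorial effects for significance (pooled-error F test)
#'
#' An unreplicated full factorial leaves no residual degrees of freedom,
#' so an error mean square is formed by pooling terms presumed inert --
#' conventionally high-order interactions with small effects. Each
#' remaining term is then tested with `F = SS(term) / error MS` on
#' (1, pool df) degrees of freedom.
#'
#' The default pool contains every interaction (order >= 2) whose
#' absolute effect does not rank in the top half of all non-intercept
#' effects. Pass `pool` explicitly to override.
#'
#' @param design A `factorial_design` with responses.
#' @param pool Character vector of term labels to pool into the error
#'   term, or `NULL` for the default rule.
#' @param alpha Significance level for the F comparison (default 0.05).
#' @return An `effect_screen`: data frame with one row per non-intercept
#'   term (`term`, `effect`, `coefficient`, `sum_sq`, `pooled`,
#'   `f_statistic`, `significant`) plus attributes `pooled_error_ms`,
#'   `pool_df`, `f_critical`, `alpha`.
#' @export
screen_effects <- function(design, pool = NULL, alpha = 0.05) {
  stopifnot(is_factorial_design(design))
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0,1)", call. = FALSE)
  model <- estimate_coefficients(design)
  n <- nrow(design$runs)
  labels <- names(model$coefficients)
  keep <- labels != "1"
  labels <- labels[keep]
  beta <- model$coefficients[keep]
  effects <- 2 * beta
  ss <- n * beta^2                       # contrast^2 / n with contrast = n*beta
  orders <- vapply(model$terms[keep], length, integer(1))

  if (is.null(pool)) {
    m <- length(labels)
    top <- labels[order(abs(effects), decreasing = TRUE)][seq_len(m %/% 2)]
    pool <- labels[orders >= 2L & !labels %in% top]
  } else {
    pool <- vapply(lapply(pool, parse_term_label), term_label, character(1))
    if (!all(pool %in% labels)) {
      stop(sprintf("pool term(s) not in design: %s",
                   paste(setdiff(pool, labels), collapse = ", ")),
           call. = FALSE)
    }
  }
  if (length(pool) == 0L) {
    stop("pool is empty: an unreplicated design needs pooled error terms",
         call. = FALSE)
  }
  if (all(labels %in% pool)) {
    stop("pool exhausts all non-intercept terms; nothing left to test",
         call. = FALSE)
  }

  pooled <- labels %in% pool
  pool_df <- sum(pooled)
  err_ms <- sum(ss[pooled]) / pool_df
  f_stat <- ifelse(pooled, NA_real_, if (err_ms > 0) ss / err_ms else NA_real_)
  if (err_ms == 0) {
    warning("pooled error mean square is zero; F statistics undefined")
  }
  f_crit <- stats::qf(1 - alpha, 1, pool_df)
  out <- data.frame(
    term = labels, effect = as.numeric(effects),
    coefficient = as.numeric(beta), sum_sq = as.numeric(ss),
    pooled = pooled, f_statistic = as.numeric(f_stat),
    significant = !pooled & !is.na(f_stat) & f_stat > f_crit,
    stringsAsFactors = FALSE
  )
  structure(out, class = c("effect_screen", "data.frame"),
            pooled_error_ms = err_ms, pool_df = pool_df,
            f_critical = f_crit, alpha = alpha)
}

#' Drop factors from a fitted factorial model
#'
#' Removes every term that involves any of the named factors; remaining
#' coefficients are unchanged, which is exact for +/-1-coded full
#' factorials because the model-term columns are orthogonal (a
#' least-squares refit of the reduced term set returns identical
#' values). Setting a factor's coded value to zero in the full equation
#' gives the same reduced polynomial.
#'
#' @param model A `factorial_model`.
#' @param drop_factors Character vector of factor names (or `Xi` labels)
#'   to remove.
#' @return The reduced `factorial_model`. The factor list is retained in
#'   full so coded indices and decoding stay valid.
#' @export
reduce_model <- function(model, drop_factors) {
  stopifnot(is_factorial_model(model))
  if (length(drop_factors) == 0L) return(model)
  nms <- vapply(model$factors, `[[`, character(1), "name")
  idx <- vapply(drop_factors, function(d) {
    if (d %in% nms) return(match(d, nms))
    i <- parse_term_label(d)
    if (length(i) != 1L) stop(sprintf("cannot interpret '%s' as one factor", d),
                              call. = FALSE)
    i
  }, integer(1))
  if (length(unique(idx)) >= length(model$factors)) {
    stop("cannot drop every factor from the model", call. = FALSE)
  }
  keep <- !vapply(model$terms, function(t) any(t %in% idx), logical(1))
  factorial_model(model$terms[keep], model$coefficients[keep], model$factors)
}

#' Predict percent degradation at a coded point
#'
#' Evaluates the factorial polynomial: the sum over model terms of
#' `coefficient * prod(coded coordinates in the term)`.
#'
#' @param object A `factorial_model`.
#' @param coded_point Either a numeric vector of length `k` (one coded
#'   coordinate per factor, in factor order) or a named vector/list of
#'   coordinates by factor name; unnamed missing factors default to the
#'   centre (0).
#' @param warn_extrapolation Warn when any `|coordinate| > 1`.
#' @param ... Unused.
#' @return Predicted response (numeric scalar, or vector if
#'   `coded_point` is a matrix with `k` columns).
#' @export
predict.factorial_model <- function(object, coded_point,
                                    warn_extrapolation = TRUE, ...) {
  point <- resolve_point(object, coded_point)
  if (is.matrix(point)) {
    return(apply(point, 1L, function(p) {
      predict.factorial_model(object, p, warn_extrapolation = FALSE)
    }))
  }
  if (warn_extrapolation && any(abs(point) > 1 + 1e-12)) {
    warning("coded point lies outside [-1, 1]: model is extrapolating")
  }
  sum(vapply(seq_along(object$terms), function(i) {
    t <- object$terms[[i]]
    object$coefficients[[i]] * if (length(t)) prod(point[t]) else 1
  }, numeric(1)))
}

## Accepts positional length-k vectors, named partial vectors/lists
## (missing coordinates -> 0), or matrices with k columns.
resolve_point <- function(model, coded_point) {
  k <- length(model$factors)
  nms <- vapply(model$factors, `[[`, character(1), "name")
  if (is.matrix(coded_point)) {
    if (ncol(coded_point) != k) stop("point matrix must have k columns",
                                     call. = FALSE)
    return(coded_point)
  }
  coded_point <- unlist(coded_point)
  if (!is.null(names(coded_point)) && all(nzchar(names(coded_point)))) {
    unknown <- setdiff(names(coded_point), nms)
    if (length(unknown)) {
      stop(sprintf("unknown factor(s) in point: %s",
                   paste(unknown, collapse = ", ")), call. = FALSE)
    }
    full <- stats::setNames(numeric(k), nms)
    full[names(coded_point)] <- coded_point
    return(full)
  }
  if (length(coded_point) != k) {
    stop(sprintf("coded point must have length %d (got %d)",
                 k, length(coded_point)), call. = FALSE)
  }
  stats::setNames(as.numeric(coded_point), nms)
}

#' Render a factorial model as its regression equation
#'
#' @param model A `factorial_model`.
#' @param digits Decimal places for display (round half to even).
#' @return A single character string like
#'   `"Y = 13.62 + 4.12 X2 + 11.12 X3 + 1.62 X2X3"`.
#' @export
model_equation <- function(model, digits = 2) {
  stopifnot(is_factorial_model(model))
  co <- round(model$coefficients, digits)
  labs <- names(co)
  pieces <- character(0)
  for (i in seq_along(co)) {
    mag <- format(abs(co[[i]]), trim = TRUE)
    txt <- if (labs[i] == "1") mag else paste(mag, labs[i])
    pieces <- c(pieces,
                if (i == 1L) paste0(if (co[[i]] < 0) "-" else "", txt)
                else paste(if (co[[i]] < 0) "-" else "+", txt))
  }
  paste("Y =", paste(pieces, collapse = " "))
}

#' @export
print.factorial_model <- function(x, ...) {
  cat(sprintf("factorial model: %d terms on %d factors\n",
              length(x$terms), length(x$factors)))
  cat(" ", model_equation(x), "\n")
  invisible(x)
}

#' @export
print.effect_screen <- function(x, ...) {
  cat(sprintf(
    "effect screen: pooled error MS = %.4g on %d df, F crit(1,%d) = %.3f at alpha = %g\n",
    attr(x, "pooled_error_ms"), attr(x, "pool_df"), attr(x, "pool_df"),
    attr(x, "f_critical"), attr(x, "alpha")))
  NextMethod()
  invisible(x)
}
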