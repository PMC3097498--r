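#' Build a 2^k full factorial design in standard (Yates) order
#'
#' Constructs the complete two-level design for `k` factors as a coded
#' run matrix with entries in {-1, +1}. Runs are in standard order: the
#' first factor's column alternates sign fastest (blocks of 1), the
#' second in blocks of 2, the j-th in blocks of `2^(j-1)`. This is the
#' canonical order assumed by the Yates algorithm.
#'
#' @param factors List of [fd_factor] objects (1 to 10 of them) with
#'   unique names.
#' @return A `factorial_design`: list with `factors`, integer `runs`
#'   matrix (`2^k` rows, columns named by factor), `responses`
#'   (`NULL` until [attach_responses()]), and `order_tag`.
#' @examples
#' d <- build_full_factorial(list(
#'   fd_factor("naoh", 0.1, 1, "N"),
#'   fd_factor("time", 15, 30, "min"),
#'   fd_factor("power", 420, 700, "W")))
#' d$runs
#' @export
build_full_factorial <- function(factors) {
  if (is_fd_factor(factors)) factors <- list(factors)
  stopifnot(is.list(factors), all(vapply(factors, is_fd_factor, logical(1))))
  k <- length(factors)
  if (k < 1L || k > 10L) {
    stop("number of factors must be between 1 and 10", call. = FALSE)
  }
  nms <- vapply(factors, `[[`, character(1), "name")
  if (anyDuplicated(nms)) {
    stop(sprintf("duplicate factor name(s): %s",
                 paste(unique(nms[duplicated(nms)]), collapse = ", ")),
         call. = FALSE)
  }
  n <- 2L^k
  runs <- vapply(seq_len(k), function(j) {
    rep(rep(c(-1L, 1L), each = 2L^(j - 1L)), length.out = n)
  }, integer(n))
  runs <- matrix(runs, nrow = n, ncol = k, dimnames = list(NULL, nms))
  structure(
    list(factors = factors, runs = runs, responses = NULL,
         order_tag = "standard"),
    class = "factorial_design"
  )
}

is_factorial_design <- function(x) inherits(x, "factorial_design")

design_k <- function(design) length(design$factors)

factor_names <- function(design) {
  vapply(design$factors, `[[`, character(1), "name")
}

#' Attach observed responses to a design
#'
#' Binds a percent-degradation response vector to the design's runs,
#' preserving run order.
#'
#' @param design A `factorial_design`.
#' @param responses Numeric vector, one finite value per run.
#' @return The design with `$responses` set.
#' @export
attach_responses <- function(design, responses) {
  stopifnot(is_factorial_design(design))
  responses <- as.numeric(responses)
  n <- nrow(design$runs)
  if (length(responses) != n) {
    stop(sprintf("expected %d responses, got %d", n, length(responses)),
         call. = FALSE)
  }
  if (!all(is.finite(responses))) {
    stop("responses must all be finite", call. = FALSE)
  }
  design$responses <- responses
  design
}

#' Actual-unit run matrix of a design
#'
#' Decodes every coded column back to actual units via [decode_value()].
#'
#' @param design A `factorial_design`.
#' @return Numeric matrix, same shape as `design$runs`.
#' @export
actual_runs <- function(design) {
  stopifnot(is_factorial_design(design))
  out <- design$runs * 1.0
  for (j in seq_along(design$factors)) {
    out[, j] <- decode_value(design$runs[, j], design$factors[[j]])
  }
  out
}

## Model-matrix column for one term: elementwise product of the coded
## factor columns it names (all-ones for the intercept).
term_column <- function(runs, term) {
  if (length(term) == 0L) return(rep(1, nrow(runs)))
  col <- runs[, term[1L]]
  for (i in term[-1L]) col <- col * runs[, i]
  col
}

## Full model matrix over a term list; columns labelled "1", "X1", ...
design_model_matrix <- function(runs, terms) {
  m <- vapply(terms, function(t) term_column(runs, t) * 1.0,
              numeric(nrow(runs)))
  matrix(m, nrow = nrow(runs), dimnames = list(NULL, term_labels(terms)))
}

## Reorder arbitrary coded rows (a complete 2^k set) into standard order.
## Row identity: treat -1 as bit 0, +1 as bit 1; standard-order row i has
## bit pattern i-1 with factor 1 as the least significant bit.
standardize_runs <- function(runs, responses = NULL) {
  k <- ncol(runs)
  n <- 2L^k
  if (nrow(runs) != n) {
    stop(sprintf("a full 2^%d design needs %d runs, got %d", k, n, nrow(runs)),
         call. = FALSE)
  }
  if (!all(runs %in% c(-1, 1))) {
    stop("coded run matrix entries must be -1 or +1", call. = FALSE)
  }
  idx <- as.integer((runs > 0) %*% 2L^(seq_len(k) - 1L)) + 1L
  if (anyDuplicated(idx)) {
    stop("runs do not form a complete 2^k design (duplicate level pattern)",
         call. = FALSE)
  }
  perm <- order(idx)
  list(runs = runs[perm, , drop = FALSE],
       responses = if (!is.null(responses)) responses[perm])
}

#' @export
print.factorial_design <- function(x, ...) {
  k <- design_k(x)
  cat(sprintf("2^%d full factorial design (%d runs, %s order)\n",
              k, nrow(x$runs), x$order_tag))
  df <- as.data.frame(x$runs)
  if (!is.null(x$responses)) df$response <- x$responses
  print(df, ...)
  invisible(x)
}
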