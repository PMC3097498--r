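#' Define a two-level stress factor
#'
#' A factor is a controllable stress variable (e.g. NaOH normality,
#' irradiation time, microwave power) studied at two actual levels. The
#' low level maps to coded -1 and the high level to coded +1; all model
#' fitting happens on the coded scale, where the design columns are
#' orthogonal.
#'
#' @param name Factor name, nonempty character scalar.
#' @param low,high Actual levels in `units`; must satisfy `low < high`.
#' @param units Unit string, e.g. `"N"`, `"min"`, `"W"`. May be `""`.
#' @return An object of class `fd_factor`.
#' @examples
#' fd_factor("naoh", 0.1, 1.0, "N")
#' @export
fd_factor <- function(name, low, high, units = "") {
  stopifnot(is.character(name), length(name) == 1L, nzchar(name))
  low <- as.numeric(low)
  high <- as.numeric(high)
  if (!is.finite(low) || !is.finite(high)) {
    stop("factor levels must be finite numbers", call. = FALSE)
  }
  if (low >= high) {
    stop(sprintf("factor '%s': low level (%g) must be < high level (%g)",
                 name, low, high), call. = FALSE)
  }
  structure(
    list(name = name, low = low, high = high, units = as.character(units)),
    class = "fd_factor"
  )
}

#' @export
print.fd_factor <- function(x, ...) {
  cat(sprintf("<factor> %s: %g (-1) .. %g (+1) %s\n",
              x$name, x$low, x$high, x$units))
  invisible(x)
}

is_fd_factor <- function(x) inherits(x, "fd_factor")

#' Convert an actual factor setting to its coded value
#'
#' Applies the midpoint/half-range transformation
#' `(actual - (low + high)/2) / ((high - low)/2)`, so that the low level
#' codes to -1, the high level to +1 and the midpoint to 0. Values
#' outside `[low, high]` are allowed (they code outside `[-1, 1]`);
#' extrapolation policy is the caller's concern.
#'
#' @param actual Numeric vector of settings in actual units.
#' @param factor An [fd_factor].
#' @return Numeric vector of coded values.
#' @seealso [decode_value()] for the exact inverse.
#' @examples
#' f <- fd_factor("power", 420, 700, "W")
#' code_value(c(420, 560, 700, 525), f)  # -1, 0, +1, -0.25
#' @export
code_value <- function(actual, factor) {
  stopifnot(is_fd_factor(factor))
  (actual - (factor$low + factor$high) / 2) / ((factor$high - factor$low) / 2)
}

#' Convert a coded factor setting back to actual units
#'
#' Exact inverse of [code_value()]:
#' `actual = coded * (high - low)/2 + (low + high)/2`.
#'
#' @param coded Numeric vector of coded values.
#' @param factor An [fd_factor].
#' @return Numeric vector in actual units.
#' @examples
#' decode_value(0, fd_factor("naoh", 0.1, 1.0, "N"))  # 0.55
#' @export
decode_value <- function(coded, factor) {
  stopifnot(is_fd_factor(factor))
  coded * (factor$high - factor$low) / 2 + (factor$low + factor$high) / 2
}

## ---- term bookkeeping ----------------------------------------------------

## A model term is an integer vector of 1-based factor indices; integer(0)
## is the intercept. Labels use the compact field convention "1", "X2",
## "X2X3", ...

term_label <- function(idx) {
  if (length(idx) == 0L) return("1")
  paste0("X", sort(idx), collapse = "")
}

parse_term_label <- function(label) {
  label <- trimws(label)
  if (label %in% c("1", "(Intercept)", "")) return(integer(0))
  if (!grepl("^(X[0-9]+)+$", label)) {
    stop(sprintf("malformed term label '%s'", label), call. = FALSE)
  }
  idx <- as.integer(regmatches(label, gregexpr("[0-9]+", label))[[1L]])
  if (anyDuplicated(idx)) {
    stop(sprintf("term label '%s' repeats a factor", label), call. = FALSE)
  }
  sort(idx)
}

## All 2^k terms, intercept first, then by interaction order and
## lexicographic factor index (1, X1, X2, X3, X1X2, X1X3, X2X3, X1X2X3).
all_terms <- function(k) {
  out <- list(integer(0))
  for (ord in seq_len(k)) {
    combs <- utils::combn(k, ord, simplify = FALSE)
    out <- c(out, lapply(combs, as.integer))
  }
  out
}

term_labels <- function(terms) vapply(terms, term_label, character(1))
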