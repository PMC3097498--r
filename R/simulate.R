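## Seeded generators. Each accepts `seed = NULL`; when a seed is given
## the global RNG state is saved and restored, so simulation calls do
## not perturb the caller's random stream.

with_seed <- function(seed, expr) {
  if (is.null(seed)) return(expr)
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(seed)
  expr
}

#' Simulate responses for a factorial design from known coefficients
#'
#' Generates `y = X beta + e`, `e ~ N(0, noise_sd^2)` i.i.d., where `X`
#' is the coded model matrix of the design over the given terms. With
#' `noise_sd = 0` the responses are exactly the model surface at the
#' design corners, so a saturated refit recovers `true_coefficients`
#' to machine precision -- the basis of all parameter-recovery checks.
#'
#' @param design A `factorial_design` (responses ignored).
#' @param true_coefficients Named numeric vector of coefficients; names
#'   are term labels (`"1"`, `"X1"`, `"X2X3"`, ...). Terms absent from
#'   the name set have coefficient zero.
#' @param noise_sd Standard deviation of the additive Gaussian noise
#'   (percent-degradation units), `>= 0`.
#' @param seed Optional integer seed; output is a deterministic
#'   function of (design, coefficients, noise_sd, seed).
#' @param clip_at_zero Truncate negative simulated responses at zero.
#'   Off by default: the estimation theory assumes unclipped normals.
#' @return Numeric response vector of length `2^k`, standard order.
#' @export
simulate_factorial_responses <- function(design, true_coefficients,
                                         noise_sd = 0, seed = NULL,
                                         clip_at_zero = FALSE) {
  stopifnot(is_factorial_design(design))
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  if (is.null(names(true_coefficients)) ||
      !all(nzchar(names(true_coefficients)))) {
    stop("true_coefficients must be named by term label", call. = FALSE)
  }
  k <- design_k(design)
  terms <- lapply(names(true_coefficients), parse_term_label)
  bad <- vapply(terms, function(t) length(t) && max(t) > k, logical(1))
  if (any(bad)) {
    stop("coefficient term refers to a factor outside the design",
         call. = FALSE)
  }
  X <- design_model_matrix(design$runs, terms)
  mu <- as.numeric(X %*% as.numeric(true_coefficients))
  y <- with_seed(seed, mu + stats::rnorm(length(mu), 0, noise_sd))
  if (clip_at_zero) y <- pmax(y, 0)
  y
}

#' Simulate a days x replicates recovery panel
#'
#' One-way random-effects structure matching what the precision ANOVA
#' assumes: `value[d, r] = true_level + B_d + e[d, r]` with day effects
#' `B_d ~ N(0, between_day_sd^2)` and replicate errors
#' `e ~ N(0, within_day_sd^2)`, all independent. Under this model the
#' expected between mean square is
#' `n_reps * between_day_sd^2 + within_day_sd^2` and the expected within
#' mean square is `within_day_sd^2`.
#'
#' @param true_level True amount found (mg).
#' @param between_day_sd,within_day_sd Nonnegative standard deviations.
#' @param n_days,n_reps Panel dimensions (default 3 x 3).
#' @param seed Optional integer seed.
#' @return Numeric matrix, rows = days.
#' @export
simulate_recovery_panel <- function(true_level, between_day_sd = 0,
                                    within_day_sd = 1, n_days = 3,
                                    n_reps = 3, seed = NULL) {
  if (between_day_sd < 0 || within_day_sd < 0) {
    stop("standard deviations must be >= 0", call. = FALSE)
  }
  if (n_days < 2 || n_reps < 2) {
    stop("need at least 2 days and 2 replicates", call. = FALSE)
  }
  with_seed(seed, {
    day_eff <- stats::rnorm(n_days, 0, between_day_sd)
    eps <- matrix(stats::rnorm(n_days * n_reps, 0, within_day_sd),
                  nrow = n_days)
    true_level + day_eff + eps
  })
}

#' Simulate calibration concentration/area pairs
#'
#' `area = slope * conc + intercept + N(0, noise_sd)`. Defaults
#' reproduce a typical rebamipide HPLC-UV calibration over
#' 0.5-5 micrograms per mL.
#'
#' @param slope Area counts per unit concentration.
#' @param intercept Area counts at zero concentration.
#' @param noise_sd Gaussian area noise, `>= 0`.
#' @param concentrations Nonempty numeric vector.
#' @param seed Optional integer seed.
#' @return Data frame with columns `concentration`, `area`.
#' @export
simulate_calibration <- function(slope = 601211, intercept = 41127,
                                 noise_sd = 0,
                                 concentrations = c(0.5, 1, 2, 3, 4, 5),
                                 seed = NULL) {
  if (length(concentrations) == 0L) {
    stop("concentrations must be nonempty", call. = FALSE)
  }
  if (noise_sd < 0) stop("noise_sd must be >= 0", call. = FALSE)
  area <- with_seed(seed, slope * concentrations + intercept +
                      stats::rnorm(length(concentrations), 0, noise_sd))
  data.frame(concentration = as.numeric(concentrations),
             area = as.numeric(area))
}
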