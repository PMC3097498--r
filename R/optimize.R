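#' Solve the fitted model for one factor at a target response
#'
#' A two-level factorial polynomial is linear in any single coded
#' coordinate once the others are fixed, so the setting that achieves a
#' target response has the closed form
#' `solved = (target - A) / B`, where `A` is the model evaluated over
#' the terms *not* containing the solved factor and `B` is the sum of
#' the coefficients of terms containing it, each multiplied by the fixed
#' coordinates of its remaining factors. Every solution is verified by
#' back-substitution through [predict.factorial_model()].
#'
#' @param model A `factorial_model`.
#' @param target_y Target response (percent degradation).
#' @param fixed Named numeric vector/list of coded coordinates for the
#'   other factors. Factors neither fixed nor solved sit at the centre
#'   (coded 0).
#' @param solve_name Name of the factor to solve for.
#' @return A `contour_solution`: list with `target_y`, `fixed_coords`,
#'   `solved_factor`, `solved_coded`, `solved_actual`, `units`,
#'   `in_design_space` (all coded coordinates within `[-1, 1]`).
#' @examples
#' fs <- list(fd_factor("naoh", 0.1, 1, "N"),
#'            fd_factor("time", 15, 30, "min"),
#'            fd_factor("power", 420, 700, "W"))
#' m <- factorial_model(c("1", "X2", "X3", "X2X3"),
#'                      c(13.62, 4.12, 11.12, 1.62), fs)
#' solve_for_factor(m, 10, fixed = c(time = 0), solve_name = "power")
#' @export
solve_for_factor <- function(model, target_y, fixed = numeric(0), solve_name) {
  stopifnot(is_factorial_model(model))
  nms <- vapply(model$factors, `[[`, character(1), "name")
  s <- match(solve_name, nms)
  if (is.na(s)) {
    stop(sprintf("factor '%s' is not in the model", solve_name), call. = FALSE)
  }
  fixed <- unlist(fixed)
  if (length(fixed) && (is.null(names(fixed)) || !all(names(fixed) %in% nms))) {
    stop("fixed coordinates must be named by factor", call. = FALSE)
  }
  if (solve_name %in% names(fixed)) {
    stop("the solved factor cannot also be fixed", call. = FALSE)
  }
  in_model <- sort(unique(unlist(model$terms)))
  if (!s %in% in_model) {
    stop(sprintf("factor '%s' appears in no model term; cannot solve for it",
                 solve_name), call. = FALSE)
  }
  coords <- stats::setNames(numeric(length(nms)), nms)
  coords[names(fixed)] <- fixed

  base <- 0    # value of terms without the solved factor
  slope <- 0   # d(prediction)/d(solved coordinate)
  for (i in seq_along(model$terms)) {
    t <- model$terms[[i]]
    co <- model$coefficients[[i]]
    if (s %in% t) {
      rest <- setdiff(t, s)
      slope <- slope + co * if (length(rest)) prod(coords[rest]) else 1
    } else {
      base <- base + co * if (length(t)) prod(coords[t]) else 1
    }
  }
  if (abs(slope) < 1e-12) {
    stop(sprintf(
      "no solution: response is flat in '%s' at the fixed coordinates (contour parallel to axis)",
      solve_name), call. = FALSE)
  }
  solved <- (target_y - base) / slope
  coords[s] <- solved
  resid <- predict(model, coords, warn_extrapolation = FALSE) - target_y
  stopifnot(abs(resid) <= 1e-9 * max(1, abs(target_y)))
  structure(
    list(target_y = target_y,
         fixed_coords = coords[-s],
         solved_factor = solve_name,
         solved_coded = as.numeric(solved),
         solved_actual = decode_value(solved, model$factors[[s]]),
         units = model$factors[[s]]$units,
         in_design_space = all(abs(coords) <= 1 + 1e-12)),
    class = "contour_solution"
  )
}

#' @export
print.contour_solution <- function(x, ...) {
  cat(sprintf("target Y = %g%%: %s = %.4f (coded) = %.4g %s%s\n",
              x$target_y, x$solved_factor, x$solved_coded, x$solved_actual,
              x$units,
              if (x$in_design_space) "" else "  [outside design space]"))
  invisible(x)
}

#' Contour data: solved settings over a sweep grid
#'
#' For each combination of a target response and a swept coded value,
#' solves for the remaining factor. The rows of the result are the
#' iso-response (contour) lines of the fitted surface, as data rather
#' than pixels. Combinations with no solution (flat direction) are kept
#' and flagged, not dropped.
#'
#' @param model A `factorial_model`.
#' @param targets Numeric vector of target responses (nonempty).
#' @param sweep_factor Name of the factor stepped along the grid.
#' @param sweep_values Coded values for `sweep_factor` (nonempty).
#' @param solve_factor Name of the factor solved at each grid point.
#' @param fixed Named coded coordinates for any remaining factors
#'   (default: centre).
#' @return Data frame with columns `target_y`, `<sweep_factor>` (coded),
#'   `solved_coded`, `solved_actual`, `in_design_space`, `solvable`.
#' @export
contour_grid <- function(model, targets, sweep_factor, sweep_values,
                         solve_factor, fixed = numeric(0)) {
  stopifnot(is_factorial_model(model))
  if (length(targets) == 0L) stop("targets must be nonempty", call. = FALSE)
  if (length(sweep_values) == 0L) {
    stop("sweep_values must be nonempty", call. = FALSE)
  }
  grid <- expand.grid(sweep = sweep_values, target = targets,
                      KEEP.OUT.ATTRS = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    fx <- c(stats::setNames(grid$sweep[i], sweep_factor), unlist(fixed))
    sol <- tryCatch(
      solve_for_factor(model, grid$target[i], fixed = fx,
                       solve_name = solve_factor),
      error = function(e) NULL)
    data.frame(
      target_y = grid$target[i], sweep = grid$sweep[i],
      solved_coded = if (is.null(sol)) NA_real_ else sol$solved_coded,
      solved_actual = if (is.null(sol)) NA_real_ else sol$solved_actual,
      in_design_space = if (is.null(sol)) NA else sol$in_design_space,
      solvable = !is.null(sol))
  })
  out <- do.call(rbind, rows)
  names(out)[names(out) == "sweep"] <- sweep_factor
  out
}

#' Recommend actual-unit operating conditions for a target degradation
#'
#' Inverts the model for one free factor (by default the free factor
#' with the largest absolute main-effect coefficient, i.e. the strongest
#' lever), holding fixed factors at their given coded values and any
#' other factors at the centre. Solutions outside the coded cube
#' `[-1, 1]` are refused unless `allow_extrapolation = TRUE`, because
#' the model is only supported inside the design space.
#'
#' @param model A `factorial_model`.
#' @param target_y Target percent degradation.
#' @param fixed Named coded coordinates to hold (may be empty).
#' @param solve Factor to solve for; `NULL` picks the default lever.
#' @param allow_extrapolation Permit settings outside the design cube.
#' @return List with `settings` (data frame: factor, coded, actual,
#'   units), `predicted_y`, `solved_factor`, `in_design_space`.
#' @export
recommend_conditions <- function(model, target_y, fixed = numeric(0),
                                 solve = NULL, allow_extrapolation = FALSE) {
  stopifnot(is_factorial_model(model))
  nms <- vapply(model$factors, `[[`, character(1), "name")
  fixed <- unlist(fixed)
  if (length(fixed) && any(abs(fixed) > 1) && !allow_extrapolation) {
    stop("fixed coordinates outside [-1, 1]; use allow_extrapolation",
         call. = FALSE)
  }
  if (is.null(solve)) {
    in_model <- sort(unique(unlist(model$terms)))
    free <- setdiff(in_model, match(names(fixed), nms))
    if (length(free) == 0L) stop("no free factor left to solve", call. = FALSE)
    main <- vapply(free, function(i) {
      lab <- term_label(i)
      if (lab %in% names(model$coefficients)) {
        abs(model$coefficients[[lab]])
      } else 0
    }, numeric(1))
    solve <- nms[free[which.max(main)]]
  }
  sol <- solve_for_factor(model, target_y, fixed = fixed, solve_name = solve)
  if (!sol$in_design_space && !allow_extrapolation) {
    stop(sprintf(
      "target %g%% needs %s at coded %.3f, outside the design space; use allow_extrapolation or change constraints",
      target_y, solve, sol$solved_coded), call. = FALSE)
  }
  coords <- stats::setNames(numeric(length(nms)), nms)
  coords[names(sol$fixed_coords)] <- sol$fixed_coords
  coords[solve] <- sol$solved_coded
  settings <- data.frame(
    factor = nms,
    coded = as.numeric(coords),
    actual = vapply(seq_along(nms), function(i) {
      decode_value(coords[[i]], model$factors[[i]])
    }, numeric(1)),
    units = vapply(model$factors, `[[`, character(1), "units"),
    stringsAsFactors = FALSE)
  list(settings = settings,
       predicted_y = predict(model, coords, warn_extrapolation = FALSE),
       solved_factor = solve,
       in_design_space = sol$in_design_space)
}
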