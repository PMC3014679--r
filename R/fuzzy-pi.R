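#' Incremental Mamdani fuzzy-PI temperature controller
#'
#' Velocity-form fuzzy PI controller: at each sample it fuzzifies the
#' temperature error \eqn{\epsilon = T - T_{sp}} and its change
#' \eqn{\Delta\epsilon}, fires a 7 x 7 Mamdani rule base with min inference,
#' aggregates the clipped consequent areas by pointwise max and defuzzifies by
#' the discrete centroid (centre of gravity of the combined areas) to obtain a
#' pump speed *change* \eqn{\Delta U}, which is integrated onto the previous
#' speed and clamped to `[0, 100]` %.
#'
#' The default universes of discourse are the tuned design values: a narrow
#' error range of \[-1, 1\] degC (so even small deviations provoke an intense
#' response), \[-0.5, 0.5\] degC per sample for the change of error, and the
#' asymmetric \[-20, 13\] % for the speed variation -- the magnitude of the
#' lower bound exceeds the upper one because the pump must be slowed down
#' faster than it is sped up when the dissolution-heat excursion turns over.
#' Inputs are clipped to their universes before fuzzification, which together
#' with shoulder-clamped end terms guarantees that at least one rule always
#' fires.
#'
#' @param rules A [rule_table()] or a name accepted by it.
#' @param setpoint Temperature set point in degC (default 5).
#' @param eps_range,deps_range,du_range Universe bounds `c(lo, hi)` for error,
#'   change of error and speed variation.
#' @param n_grid Number of points of the output-universe discretization used
#'   by the centroid (>= 101; default 10001).
#' @param U0 Initial pump speed, % of maximum.
#' @return An object of class `c("fuzzy_pi", "controller")`.
#' @seealso [control_step()], [control_surface()], [fuzzy_infer()],
#'   [defuzzify()]
#' @export
#' @examples
#' ctrl <- fuzzy_pi("tuned")
#' st <- control_step(ctrl, 6.2)   # bulk 1.2 degC above set point
#' st$dU                           # positive: speed the coolant pump up
fuzzy_pi <- function(rules = "tuned", setpoint = 5,
                     eps_range = c(-1, 1), deps_range = c(-0.5, 0.5),
                     du_range = c(-20, 13), n_grid = 10001L, U0 = 40) {
  if (is.character(rules)) rules <- rule_table(rules)
  stopifnot(inherits(rules, "rule_table"))
  if (n_grid < 101L) abort("n_grid must be >= 101", class = "precool_config_error")
  vars <- list(
    error            = linguistic_variable("error", eps_range[1], eps_range[2]),
    change_of_error  = linguistic_variable("change_of_error", deps_range[1], deps_range[2]),
    speed_variation  = linguistic_variable("speed_variation", du_range[1], du_range[2])
  )
  u_grid <- seq(du_range[1], du_range[2], length.out = as.integer(n_grid))
  ## 7 x n_grid matrix of output-term memberships, precomputed once
  out_mat <- t(membership_matrix(u_grid, vars$speed_variation))
  structure(list(
    rules = rules, vars = vars, setpoint = setpoint,
    n_grid = as.integer(n_grid), u_grid = u_grid, out_mat = out_mat,
    state = list(prev_error = 0, prev_speed = U0)
  ), class = c("fuzzy_pi", "controller"))
}

#' Controller inputs from a temperature measurement
#'
#' Computes the error \eqn{\epsilon(t) = Y(t) - Y_{sp}} and change of error
#' \eqn{\Delta\epsilon(t) = \epsilon(t) - \epsilon(t - \Delta t)} from the
#' measured bulk temperature and the stored previous error, then clips both to
#' their universes for fuzzification. The raw (unclipped) values are returned
#' alongside; the previous error kept in the state is always the raw one.
#'
#' @param controller A [fuzzy_pi()] (or neurofuzzy) controller.
#' @param measured_T Measured bulk temperature, degC.
#' @return A list with `eps`, `deps` (clipped) and `eps_raw`, `deps_raw`.
#' @export
compute_inputs <- function(controller, measured_T) {
  ve <- controller$vars$error
  vd <- controller$vars$change_of_error
  eps_raw  <- measured_T - controller$setpoint
  deps_raw <- eps_raw - controller$state$prev_error
  list(eps  = clip_to(eps_raw, ve$lo, ve$hi),
       deps = clip_to(deps_raw, vd$lo, vd$hi),
       eps_raw = eps_raw, deps_raw = deps_raw)
}

## fast path: per-consequent-term firing strengths (length-7 numeric)
fuzzy_strengths <- function(controller, eps, deps) {
  mue <- membership_matrix(eps, controller$vars$error)[1L, ]
  mud <- membership_matrix(deps, controller$vars$change_of_error)[1L, ]
  strength <- numeric(7L)
  tab <- controller$rules
  ei <- which(mue > 0)
  dj <- which(mud > 0)
  for (i in ei) for (j in dj) {
    s <- min(mue[i], mud[j])
    k <- match(tab[i, j], fuzzy_terms())
    if (s > strength[k]) strength[k] <- s
  }
  strength
}

#' Mamdani min inference over the rule base
#'
#' Fires every rule whose antecedent memberships are both positive with
#' strength `min(mu_eps, mu_deps)`; rules sharing a consequent term are
#' aggregated by max.
#'
#' @inheritParams compute_inputs
#' @param eps,deps Error and change of error, already inside their universes.
#' @return A tibble with columns `term` and `strength`, one row per consequent
#'   term with positive strength.
#' @export
#' @examples
#' fuzzy_infer(fuzzy_pi(), 0, 0)   # only ZR fires, strength 1
fuzzy_infer <- function(controller, eps, deps) {
  s <- fuzzy_strengths(controller, eps, deps)
  tibble(term = fuzzy_terms(), strength = s) |> filter(.data$strength > 0)
}

#' Centroid defuzzification of an aggregated output area
#'
#' Clips each fired consequent membership function at its firing strength,
#' combines the clipped areas by pointwise max over a uniform discretization
#' of the output universe, and returns the centre of gravity
#' \eqn{\sum_i u_i \mu(u_i) / \sum_i \mu(u_i)}.
#'
#' @inheritParams compute_inputs
#' @param fired Tibble as returned by [fuzzy_infer()] (columns `term`,
#'   `strength`).
#' @return The crisp speed variation \eqn{\Delta U} in %, guaranteed to lie
#'   inside the output universe.
#' @export
defuzzify <- function(controller, fired) {
  strength <- numeric(7L)
  strength[match(fired$term, fuzzy_terms())] <- fired$strength
  if (all(strength <= 0)) {
    abort("no rule fired: universe coverage is broken", class = "precool_internal_error")
  }
  agg <- numeric(controller$n_grid)
  for (k in which(strength > 0)) {
    agg <- pmax(agg, pmin(controller$out_mat[k, ], strength[k]))
  }
  sum(controller$u_grid * agg) / sum(agg)
}

#' Advance a controller by one sample
#'
#' Generic single-step interface shared by all controllers in the package.
#' Controllers are immutable: the updated controller is returned together
#' with the action, and closed-loop drivers thread it through the run.
#'
#' @param controller A controller object.
#' @param measured_T Measured bulk temperature, degC.
#' @param obs Optional one-row tibble of auxiliary plant observations (used by
#'   the predictive controller; ignored by the fuzzy ones).
#' @return A list with `controller` (updated state), `U` (new pump speed, %,
#'   clamped to `[0, 100]`) and `dU` (the raw increment before clamping).
#' @export
control_step <- function(controller, measured_T, obs = NULL) {
  UseMethod("control_step")
}

#' @rdname control_step
#' @export
control_step.fuzzy_pi <- function(controller, measured_T, obs = NULL) {
  inp <- compute_inputs(controller, measured_T)
  strength <- fuzzy_strengths(controller, inp$eps, inp$deps)
  agg <- numeric(controller$n_grid)
  for (k in which(strength > 0)) {
    agg <- pmax(agg, pmin(controller$out_mat[k, ], strength[k]))
  }
  dU <- sum(controller$u_grid * agg) / sum(agg)
  U_new <- clip_to(controller$state$prev_speed + dU, 0, 100)
  controller$state$prev_error <- inp$eps_raw
  controller$state$prev_speed <- U_new
  list(controller = controller, U = U_new, dU = dU)
}

#' Constant-speed (open-loop) controller
#'
#' Holds the pump at a fixed speed; used as the open-loop baseline in
#' performance comparisons.
#'
#' @param U Pump speed, % of maximum.
#' @return An object of class `c("constant_controller", "controller")`.
#' @export
constant_controller <- function(U = 40) {
  structure(list(state = list(prev_speed = clip_to(U, 0, 100), prev_error = 0)),
            class = c("constant_controller", "controller"))
}

#' @rdname control_step
#' @export
control_step.constant_controller <- function(controller, measured_T, obs = NULL) {
  list(controller = controller, U = controller$state$prev_speed, dU = 0)
}

#' Control surface of a fuzzy (or neurofuzzy) controller
#'
#' Evaluates the static input-output map \eqn{\Delta U(\epsilon,
#' \Delta\epsilon)} on a uniform grid over the input universes.
#'
#' @param controller A [fuzzy_pi()] or neurofuzzy controller.
#' @param resolution Grid points per axis (>= 11).
#' @return A tibble of class `control_surface` with columns `epsilon`,
#'   `delta_epsilon`, `delta_u` (row-major: `epsilon` varies slowest).
#' @export
#' @examples
#' surf <- control_surface(fuzzy_pi("tuned"), resolution = 21)
#' readr::write_csv(surf, tempfile(fileext = ".csv"))
control_surface <- function(controller, resolution = 41L) {
  if (resolution < 11L) abort("resolution must be >= 11", class = "precool_config_error")
  ve <- controller$vars$error
  vd <- controller$vars$change_of_error
  grid <- tidyr::expand_grid(
    epsilon = seq(ve$lo, ve$hi, length.out = as.integer(resolution)),
    delta_epsilon = seq(vd$lo, vd$hi, length.out = as.integer(resolution))
  )
  grid$delta_u <- purrr::map2_dbl(grid$epsilon, grid$delta_epsilon,
                                  ~ evaluate_action(controller, .x, .y))
  class(grid) <- c("control_surface", class(grid))
  grid
}

#' Static controller action at given inputs
#'
#' Evaluates the crisp input-output map \eqn{\Delta U(\epsilon,
#' \Delta\epsilon)} of a fuzzy or neurofuzzy controller without touching its
#' state (inputs are clipped to the universes first). This is the map that
#' [control_surface()] samples.
#'
#' @param controller A [fuzzy_pi()] or [as_controller()] wrapper.
#' @param eps,deps Error and change of error, degC.
#' @return The speed variation \eqn{\Delta U}, %.
#' @export
evaluate_action <- function(controller, eps, deps) {
  UseMethod("evaluate_action")
}

#' @export
evaluate_action.fuzzy_pi <- function(controller, eps, deps) {
  ve <- controller$vars$error
  vd <- controller$vars$change_of_error
  eps <- clip_to(eps, ve$lo, ve$hi)
  deps <- clip_to(deps, vd$lo, vd$hi)
  strength <- fuzzy_strengths(controller, eps, deps)
  agg <- numeric(controller$n_grid)
  for (k in which(strength > 0)) {
    agg <- pmax(agg, pmin(controller$out_mat[k, ], strength[k]))
  }
  sum(controller$u_grid * agg) / sum(agg)
}

#' Plot a control surface
#'
#' @param object A [control_surface()] tibble.
#' @param ... Unused.
#' @return A ggplot raster of \eqn{\Delta U} over the input plane.
#' @export
autoplot.control_surface <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$epsilon, .data$delta_epsilon,
                                       fill = .data$delta_u)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "#2166ac", mid = "white", high = "#b2182b",
                                  name = expression(Delta * U ~ "(%)")) +
    ggplot2::labs(x = expression(epsilon ~ "(°C)"),
                  y = expression(Delta * epsilon ~ "(°C)")) +
    ggplot2::theme_minimal()
}

#' @export
print.fuzzy_pi <- function(x, ...) {
  cat(sprintf("<fuzzy-PI controller: rules '%s', setpoint %g degC, U = %g %%>\n",
              attr(x$rules, "name"), x$setpoint, x$state$prev_speed))
  invisible(x)
}
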