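#' Constraint set of the predictive controller
#'
#' Box, rate and safety constraints applied to the manipulated variable: the
#' pump speed must satisfy `U_min <= U <= U_max`, may move at most `max_step`
#' % per sample (smoothing the solver action), and is switched off entirely
#' when the bulk temperature reaches `cutoff_T` -- a guard that keeps the
#' controlled variable inside the neural model's training range.
#'
#' @param U_min,U_max Pump speed bounds, %.
#' @param max_step Maximum speed change per sample, %.
#' @param cutoff_T Pump-off temperature threshold, degC.
#' @param setpoint Temperature set point, degC.
#' @return A list of class `mpc_constraints`.
#' @export
mpc_constraints <- function(U_min = 0, U_max = 100, max_step = 35,
                            cutoff_T = 4.9, setpoint = 5) {
  stopifnot(U_min < U_max, max_step > 0)
  structure(list(U_min = U_min, U_max = U_max, max_step = max_step,
                 cutoff_T = cutoff_T, setpoint = setpoint),
            class = "mpc_constraints")
}

#' One-step-ahead model predictive controller
#'
#' At every sample the controller asks the neural model for the bulk
#' temperature one step ahead as a function of the candidate pump speed and
#' picks the speed minimizing the squared set-point deviation
#' \eqn{\min_U (\hat T_{k+1}(U) - T_{sp})^2} subject to the
#' [mpc_constraints()]. The one-dimensional bounded minimization uses a
#' coarse scan refined by golden-section/parabolic search
#' ([stats::optimize]); near-ties are broken toward the smaller move
#' `|U - U_prev|`.
#'
#' @param model A trained [mlp_model()].
#' @param constraints An [mpc_constraints()].
#' @param U0 Initial pump speed, %.
#' @return An object of class `c("mpc_controller", "controller")`.
#' @export
mpc_controller <- function(model, constraints = mpc_constraints(), U0 = 40) {
  if (!isTRUE(model$trained)) {
    abort("MPC needs a trained neural model", class = "precool_config_error")
  }
  structure(list(model = model, constraints = constraints,
                 state = list(prev_speed = U0, prev_error = 0)),
            class = c("mpc_controller", "controller"))
}

#' Solve one predictive-control step
#'
#' Exposed separately so the optimizer can be validated against an exhaustive
#' grid search. Returns the pump speed for the next interval given the
#' current observation row.
#'
#' @param model A trained [mlp_model()].
#' @param obs One-row data frame/tibble with at least `T_bulk`, `V`,
#'   `T_out`, and optionally `T_in`, `T_eth` (defaulting to 0 and 23 degC).
#' @param U_prev Previous pump speed, %.
#' @param constraints An [mpc_constraints()].
#' @param n_scan Points of the coarse feasibility scan.
#' @return A list: `U` (chosen speed), `cutoff` (TRUE when the
#'   low-temperature rule fired), `lb`, `ub` (the feasible interval).
#' @export
mpc_step <- function(model, obs, U_prev, constraints = mpc_constraints(),
                     n_scan = 41L) {
  cn <- constraints
  if (obs$T_bulk <= cn$cutoff_T) {
    return(list(U = 0, cutoff = TRUE, lb = 0, ub = 0))
  }
  lb <- max(cn$U_min, U_prev - cn$max_step)
  ub <- min(cn$U_max, U_prev + cn$max_step)
  if (lb > ub) abort("empty feasible interval", class = "precool_internal_error")
  f <- mpc_objective(model, obs, U_prev, cn)
  U <- solve_bounded_scalar(f, lb, ub, prefer = U_prev, n_scan = n_scan)
  list(U = U, cutoff = FALSE, lb = lb, ub = ub)
}

## squared one-step set-point deviation as a function of candidate U
mpc_objective <- function(model, obs, U_prev, constraints) {
  T_in <- if ("T_in" %in% names(obs)) obs$T_in else 0
  T_alc <- if ("T_eth" %in% names(obs)) obs$T_eth else 23
  function(U) {
    X <- cbind(T_alc = T_alc, T_in = T_in, T_out = obs$T_out, U = U,
               L = obs$V, dU = U - U_prev, T_bulk = obs$T_bulk)
    (mlp_predict(model, X) - constraints$setpoint)^2
  }
}

## coarse scan + local refinement; near-ties (within tol) go to the value
## closest to `prefer`
solve_bounded_scalar <- function(f, lb, ub, prefer, n_scan = 41L, tol = 1e-9) {
  if (ub - lb < 1e-12) return(lb)
  us <- seq(lb, ub, length.out = n_scan)
  fs <- vapply(us, f, numeric(1))
  cand <- us[which(fs <= min(fs) + tol)]
  u_best <- cand[which.min(abs(cand - prefer))]
  i <- which.min(abs(us - u_best))
  blo <- us[max(i - 1L, 1L)]; bhi <- us[min(i + 1L, n_scan)]
  opt <- optimize(f, c(blo, bhi), tol = 1e-10)
  pts <- c(opt$minimum, u_best, lb, ub)
  vals <- vapply(pts, f, numeric(1))
  winners <- pts[vals <= min(vals) + tol]
  winners[which.min(abs(winners - prefer))]
}

#' @rdname control_step
#' @export
control_step.mpc_controller <- function(controller, measured_T, obs = NULL) {
  if (is.null(obs)) {
    abort("mpc controller needs plant observations", class = "precool_config_error")
  }
  obs$T_bulk <- measured_T
  st <- mpc_step(controller$model, obs, controller$state$prev_speed,
                 controller$constraints)
  dU <- st$U - controller$state$prev_speed
  controller$state$prev_speed <- st$U
  controller$state$prev_error <- measured_T - controller$constraints$setpoint
  list(controller = controller, U = st$U, dU = dU, cutoff = st$cutoff)
}

#' Open-loop staircase controller
#'
#' Plays back a fixed pump-speed schedule (one value per sample), used to
#' generate the step-disturbance batches that train the neural model.
#'
#' @param schedule Numeric vector of pump speeds, %, one per sample; the last
#'   value is held beyond the end.
#' @return An object of class `c("schedule_controller", "controller")`.
#' @export
schedule_controller <- function(schedule) {
  structure(list(schedule = clip_to(schedule, 0, 100),
                 state = list(prev_speed = schedule[1], prev_error = 0, k = 0L)),
            class = c("schedule_controller", "controller"))
}

#' @rdname control_step
#' @export
control_step.schedule_controller <- function(controller, measured_T, obs = NULL) {
  k <- controller$state$k + 1L
  U <- controller$schedule[min(k, length(controller$schedule))]
  dU <- U - controller$state$prev_speed
  controller$state$k <- k
  controller$state$prev_speed <- U
  list(controller = controller, U = U, dU = dU)
}

#' Simulated database for the neural model
#'
#' Produces the run collection the network is trained on: open-loop
#' fed-batch runs driven by planned pump-speed staircases spanning the whole
#' actuation range 0-100 % (training role), plus closed-loop runs under the
#' tuned fuzzy-PI controller (test role), mirroring the design in which the
#' neural model must also be adequate in closed-loop situations.
#'
#' @param params Calibrated [plant_params()].
#' @param seed Seed for the staircase plans.
#' @param n_staircase Number of open-loop staircase batches.
#' @param closed_T0 Initial temperatures of the closed-loop test batches,
#'   degC.
#' @param duration Batch duration, s.
#' @return List of run logs, each with a `role` attribute
#'   (`"train"`/`"test"`).
#' @export
mpc_training_runs <- function(params, seed = 1L, n_staircase = 6L,
                              closed_T0 = c(5, 7), duration = 1200) {
  set.seed(seed)
  n_samp <- floor(duration / params$sample_dt)
  runs <- list()
  for (i in seq_len(n_staircase)) {
    n_steps <- 8L
    levels <- runif(n_steps, 0, 100)
    levels[sample.int(n_steps, 2L)] <- c(0, 100)   # guarantee range coverage
    hold <- diff(round(seq(0, n_samp, length.out = n_steps + 1L)))
    sched <- rep(levels, times = hold)
    lg <- run_fed_batch(schedule_controller(sched), params, duration = duration,
                        T0 = params$setpoint + runif(1, -1, 2))
    attr(lg, "role") <- "train"
    runs[[length(runs) + 1L]] <- lg
  }
  for (T0 in closed_T0) {
    lg <- run_fed_batch(fuzzy_pi("tuned", setpoint = params$setpoint), params,
                        duration = duration, T0 = T0)
    attr(lg, "role") <- "test"
    runs[[length(runs) + 1L]] <- lg
  }
  runs
}
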