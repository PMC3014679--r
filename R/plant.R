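#' Plant parameters for the fed-batch precipitation tank
#'
#' Lumped single-compartment model of a 1 L jacketed stirred tank in which
#' 150 mL of aqueous extract is fed with ethanol at 2.16 L/h (0.6 mL/s) until
#' the volume reaches 750 mL (a 1:4 v/v extract:ethanol batch of about 17
#' minutes), while chilled coolant at 0 degC is pumped through the jacket by a
#' variable-speed pump (the manipulated variable, % of maximum speed).
#'
#' The energy balance is
#' \deqn{\rho c_p V \frac{dT}{dt} = A_f (T_{eth} - T) + Q_d(V)
#'       - K(V)\,(U/100)^{\gamma(V)}\,(T - T_{c,in})}
#' with an ethanol sensible-heat load \eqn{A_f = c_{p,eth} F_{eth}}, a
#' dissolution-heat release \eqn{Q_d(V)} that is largest at the start of the
#' batch and decays with dilution, and a jacket duty whose scale \eqn{K(V)}
#' grows with the wetted area and whose pump-speed exponent
#' \eqn{\gamma(V)} grows with volume. \eqn{K, \gamma, Q_d} are quadratic
#' functions of volume identified by [calibrate_plant()] from the published
#' reaction-curve static gains; `plant_params()` returns them uncalibrated
#' (`calibration = NULL`) and [default_plant()] returns the calibrated set.
#'
#' In *pseudosteady* (reaction-curve) mode the volume is held constant by
#' adding and withdrawing prediluted extract at equal rates; this exchange
#' stream enters at `T_exch` degC with heat-capacity flow `W_exch` W/degC and
#' is absent in fed-batch mode.
#'
#' @param V0 Initial (extract) volume, mL.
#' @param V_max Final volume, mL.
#' @param F_eth Ethanol feed rate, mL/s (2.16 L/h).
#' @param T_eth Ethanol temperature, degC (room temperature).
#' @param T_cool_in Coolant inlet temperature, degC.
#' @param setpoint Bulk temperature set point, degC.
#' @param rho_cp Volumetric heat capacity of the bulk, J/(mL degC).
#' @param cp_eth Volumetric heat capacity of the ethanol feed, J/(mL degC).
#' @param W_exch Pseudosteady exchange-stream heat-capacity flow, W/degC.
#' @param T_exch Pseudosteady exchange-stream temperature, degC.
#' @param U0 Nominal pump speed at which reaction curves start, %.
#' @param Wc_max Coolant heat-capacity flow at 100 % pump, W/degC (used only
#'   to report the coolant outlet temperature).
#' @param P_max Pump motor power at 100 % speed, kW (energy proxy).
#' @param sample_dt Controller sample time, s.
#' @param ode_dt Integrator step, s; must divide `sample_dt`.
#' @param noise_sd Std. dev. of Gaussian measurement noise fed to the
#'   controller, degC (0 = deterministic).
#' @param calibration Calibration block as produced by [calibrate_plant()],
#'   or `NULL`.
#' @return A list of class `plant_params`.
#' @export
plant_params <- function(V0 = 150, V_max = 750, F_eth = 0.6, T_eth = 23,
                         T_cool_in = 0, setpoint = 5, rho_cp = 3.2,
                         cp_eth = 2.4, W_exch = 5.56, T_exch = 0, U0 = 40,
                         Wc_max = 374, P_max = 0.75,
                         sample_dt = 4, ode_dt = 0.25, noise_sd = 0,
                         calibration = NULL) {
  p <- list(V0 = V0, V_max = V_max, F_eth = F_eth, T_eth = T_eth,
            T_cool_in = T_cool_in, setpoint = setpoint, rho_cp = rho_cp,
            cp_eth = cp_eth, A_feed = cp_eth * F_eth,
            W_exch = W_exch, T_exch = T_exch, U0 = U0,
            Wc_max = Wc_max, P_max = P_max,
            sample_dt = sample_dt, ode_dt = ode_dt, noise_sd = noise_sd,
            calibration = calibration)
  stopifnot(V0 > 0, V_max > V0, F_eth > 0, rho_cp > 0, cp_eth > 0,
            sample_dt > 0, ode_dt > 0)
  if (abs(sample_dt / ode_dt - round(sample_dt / ode_dt)) > 1e-9) {
    abort("ode_dt must divide sample_dt", class = "precool_config_error")
  }
  structure(p, class = "plant_params")
}

#' Published reaction-curve static gains
#'
#' The six static gains (degC per % of pump speed) measured from process
#' reaction curves at three constant volumes with +30 % and -30 % pump-speed
#' steps from the 40 % nominal. Gains follow the reaction-curve table
#' convention: signed by the direction of the temperature response,
#' i.e. \eqn{K_p = \Delta T_{ss} / |\Delta U|}, so positive steps (more
#' cooling) give negative gains and negative steps positive ones.
#'
#' @return A tibble with columns `V_mL`, `dilution`, `dU_pct`, `Kp`.
#' @export
#' @examples
#' gain_targets()
gain_targets <- function() {
  tibble(
    V_mL = rep(c(300, 450, 600), each = 2),
    dilution = rep(c("1:1", "1:2", "1:3"), each = 2),
    dU_pct = rep(c(30, -30), 3),
    Kp = c(-0.030, 0.030, -0.047, 0.020, -0.053, 0.010)
  )
}

## evaluate the quadratic volume laws of a calibration block
cal_coef <- function(V, cf) cf[1] + cf[2] * V + cf[3] * V^2
plant_K   <- function(V, p) pmax(cal_coef(V, p$calibration$K_coef),  0.3)
plant_gam <- function(V, p) pmax(cal_coef(V, p$calibration$gam_coef), 0.05)
plant_Qd  <- function(V, p) pmax(cal_coef(V, p$calibration$Qd_coef), 0) *
  p$calibration$q_scale

need_calibration <- function(params) {
  if (is.null(params$calibration)) {
    abort("plant is not calibrated; run calibrate_plant() or use default_plant()",
          class = "precool_config_error")
  }
}

#' Calibrate the plant model to reaction-curve static gains
#'
#' Identifies the volume-dependent jacket duty and dissolution heat from the
#' six published static gains. At each test volume the three local parameters
#' (cooling scale \eqn{K_V}, pump exponent \eqn{\gamma_V}, dissolution heat
#' \eqn{Q_{d,V}}) are solved *exactly* from three conditions: the pseudosteady
#' curve starts at the set point at the nominal pump speed, and the +30 % and
#' -30 % steps reproduce the printed gains. The pump exponent is found by a
#' bracketed root search ([stats::uniroot]); the other two then follow in
#' closed form. A quadratic in volume through the three solved values of each
#' parameter gives the continuous plant used in fed-batch mode.
#'
#' @param params A [plant_params()].
#' @param targets Gain table in the format of [gain_targets()].
#' @param tol Root-search tolerance on the pump exponent.
#' @return `params` with a `calibration` block: per-volume solution table and
#'   quadratic coefficients (`K_coef`, `gam_coef`, `Qd_coef`), plus the
#'   analytic gain residuals.
#' @export
#' @examples
#' p <- calibrate_plant(plant_params())
#' tidy(p$calibration)
calibrate_plant <- function(params = plant_params(), targets = gain_targets(),
                            tol = 1e-12) {
  a_tot <- params$A_feed + params$W_exch        # total through-flow, W/degC
  Tsp <- params$setpoint
  u0 <- params$U0 / 100
  wide <- targets |>
    tidyr::pivot_wider(names_from = "dU_pct", values_from = "Kp",
                       names_prefix = "dU") |>
    arrange(.data$V_mL)
  if (!all(c("dU30", "dU-30") %in% names(wide))) {
    abort("targets must contain +30 and -30 steps for each volume",
          class = "precool_config_error")
  }
  sol <- purrr::pmap(wide, function(V_mL, dilution, dU30, `dU-30`, ...) {
    dTp <- dU30 * 30          # temperature change for the +30 step
    dTn <- `dU-30` * 30       # ... and the -30 step (table convention |dU|)
    up <- u0 + 0.30; un <- u0 - 0.30
    ## K/a_tot implied by each step as a function of gamma; root at equality
    wa_of <- function(g, dT, u) -dT / ((Tsp + dT) * u^g - Tsp * u0^g)
    f <- function(g) wa_of(g, dTp, up) - wa_of(g, dTn, un)
    gs <- seq(0.05, 30, by = 0.05)
    fv <- vapply(gs, f, numeric(1))
    sgn <- which(diff(sign(fv)) != 0)
    ## keep the physical branch: positive cooling scale
    g <- NA_real_
    for (s in sgn) {
      root <- uniroot(f, c(gs[s], gs[s + 1]), tol = tol)$root
      if (wa_of(root, dTp, up) > 0) { g <- root; break }
    }
    if (!is.finite(g)) {
      abort(sprintf("calibration failed at V = %g mL: no feasible pump exponent", V_mL),
            class = "precool_calibration_error")
    }
    K <- wa_of(g, dTp, up) * a_tot
    ## anchor: T_ss(U0) = setpoint in pseudosteady mode
    Qd <- Tsp * (a_tot + K * u0^g) - params$T_eth * params$A_feed -
      params$W_exch * params$T_exch
    tibble(V_mL = V_mL, dilution = dilution, K = K, gamma = g, Qd = Qd)
  }) |> dplyr::bind_rows()
  if (any(sol$Qd < 0)) {
    abort("calibration produced a negative dissolution heat; increase W_exch",
          class = "precool_calibration_error")
  }
  vand <- cbind(1, sol$V_mL, sol$V_mL^2)
  cal <- list(
    volumes = sol,
    K_coef = solve(vand, sol$K),
    gam_coef = solve(vand, sol$gamma),
    Qd_coef = solve(vand, sol$Qd),
    q_scale = 1,
    targets = targets
  )
  params$calibration <- cal
  params$calibration$residuals <- calibration_residuals(params)
  class(params$calibration) <- "plant_calibration"
  params
}

## analytic steady-state gain residuals vs the targets (pseudosteady balance)
calibration_residuals <- function(params) {
  tg <- params$calibration$targets
  tg$Kp_model <- purrr::map2_dbl(tg$V_mL, tg$dU_pct, function(V, dU) {
    Ti <- pseudosteady_Tss(params, V, params$U0)
    Tf <- pseudosteady_Tss(params, V, params$U0 + dU)
    (Tf - Ti) / abs(dU)
  })
  tg$residual <- tg$Kp_model - tg$Kp
  tg
}

## closed-form pseudosteady steady state at constant volume
pseudosteady_Tss <- function(params, V, U) {
  p <- params
  num <- p$A_feed * p$T_eth + p$W_exch * p$T_exch + plant_Qd(V, p) +
    plant_K(V, p) * (U / 100)^plant_gam(V, p) * p$T_cool_in
  den <- p$A_feed + p$W_exch + plant_K(V, p) * (U / 100)^plant_gam(V, p)
  num / den
}

#' Calibrated default plant
#'
#' [plant_params()] calibrated to [gain_targets()]; the configuration used by
#' all examples and experiments unless overridden.
#'
#' @param ... Passed to [plant_params()].
#' @return A calibrated `plant_params` object.
#' @export
default_plant <- function(...) calibrate_plant(plant_params(...))

#' Tidy / glance methods for a plant calibration
#'
#' @param x A `plant_calibration` (the `calibration` element of a calibrated
#'   [plant_params()]).
#' @param ... Unused.
#' @return `tidy()`: the per-volume parameter table; `glance()`: one row with
#'   the worst absolute gain residual.
#' @export
tidy.plant_calibration <- function(x, ...) as_tibble(x$volumes)

#' @rdname tidy.plant_calibration
#' @export
glance.plant_calibration <- function(x, ...) {
  tibble(n_gains = nrow(x$residuals),
         max_abs_residual = max(abs(x$residuals$residual)))
}

#' Energy-balance derivatives of the plant state
#'
#' Right-hand side of the lumped model. In fed-batch mode the volume grows at
#' the ethanol feed rate until `V_max`; in pseudosteady mode it is constant
#' and the extract exchange stream is active.
#'
#' @param state List or one-row tibble with `T_bulk` (degC) and `V` (mL).
#' @param U Pump speed, % (clamped to `[0, 100]`).
#' @param params Calibrated [plant_params()].
#' @param mode `"fed_batch"` or `"pseudosteady"`.
#' @return List with `dT` (degC/s), `dV` (mL/s) and the flux breakdown
#'   (`Q_feed`, `Q_diss`, `Q_cool`, `Q_exch`, all W) plus the reported coolant
#'   outlet temperature `T_out`.
#' @export
plant_derivatives <- function(state, U, params, mode = c("fed_batch", "pseudosteady")) {
  mode <- match.arg(mode)
  need_calibration(params)
  T <- state$T_bulk; V <- state$V
  if (V <= 0) abort("nonphysical state: V <= 0", class = "precool_simulation_error")
  U <- clip_to(U, 0, 100)
  Q_feed <- params$A_feed * (params$T_eth - T)
  Q_diss <- plant_Qd(V, params)
  Q_cool <- plant_K(V, params) * (U / 100)^plant_gam(V, params) * (T - params$T_cool_in)
  Q_exch <- if (mode == "pseudosteady") params$W_exch * (params$T_exch - T) else 0
  dT <- (Q_feed + Q_diss + Q_exch - Q_cool) / (params$rho_cp * V)
  dV <- if (mode == "fed_batch" && V < params$V_max) params$F_eth else 0
  Wc <- params$Wc_max * max(U / 100, 0.02)
  list(dT = dT, dV = dV, Q_feed = Q_feed, Q_diss = Q_diss, Q_cool = Q_cool,
       Q_exch = Q_exch, T_out = params$T_cool_in + Q_cool / Wc)
}

## one fixed-step RK4 update of (T, V) over h seconds at constant U
rk4_step <- function(T, V, U, h, params, mode) {
  f <- function(T, V) {
    d <- plant_derivatives(list(T_bulk = T, V = V), U, params, mode)
    c(d$dT, d$dV)
  }
  capV <- function(V) min(V, params$V_max)
  k1 <- f(T, V)
  k2 <- f(T + h / 2 * k1[1], capV(V + h / 2 * k1[2]))
  k3 <- f(T + h / 2 * k2[1], capV(V + h / 2 * k2[2]))
  k4 <- f(T + h * k3[1], capV(V + h * k3[2]))
  c(T + h / 6 * (k1[1] + 2 * k2[1] + 2 * k3[1] + k4[1]),
    capV(V + h / 6 * (k1[2] + 2 * k2[2] + 2 * k3[2] + k4[2])))
}

#' Run a closed-loop fed-batch precipitation
#'
#' Integrates the plant with fixed-step RK4, consulting the controller every
#' `sample_dt` seconds. The controller sees the measured bulk temperature
#' (plus optional Gaussian noise) and sets the pump speed for the next sample
#' interval. Actions outside `[0, 100]` % are clamped and flagged.
#'
#' @param controller A controller ([fuzzy_pi()], [as_controller()],
#'   [mpc_controller()], [constant_controller()], ...).
#' @param params Calibrated [plant_params()].
#' @param duration Batch duration, s (>= the 1000 s fill time by default).
#' @param T0 Initial bulk temperature, degC (defaults to the set point).
#' @return A run-log tibble (class `runlog`) with columns `t_s`, `T_bulk_C`,
#'   `V_mL`, `U_pct`, `dU_pct`, `T_in_C`, `T_out_C`, `T_eth_C` and a logical
#'   `clamped`; samples at t = 0, sample_dt, ...
#' @export
#' @examples
#' plant <- default_plant()
#' log <- run_fed_batch(fuzzy_pi("tuned"), plant, duration = 400)
#' performance_report(log, controller_name = "fuzzy-tuned")
run_fed_batch <- function(controller, params, duration = 1200, T0 = NULL) {
  need_calibration(params)
  if (is.null(T0)) T0 <- params$setpoint
  dt <- params$sample_dt
  n_sub <- round(dt / params$ode_dt)
  n <- floor(duration / dt)
  T <- T0; V <- params$V0
  t_s <- T_bulk <- V_mL <- U_pct <- dU_pct <- T_out <- numeric(n)
  clamped <- cutoff <- logical(n)
  for (k in seq_len(n)) {
    measured <- T + if (params$noise_sd > 0) rnorm(1, 0, params$noise_sd) else 0
    d0 <- plant_derivatives(list(T_bulk = T, V = V), controller$state$prev_speed,
                            params, "fed_batch")
    obs <- tibble(T_bulk = measured, V = V, t = (k - 1) * dt, T_out = d0$T_out,
                  T_in = params$T_cool_in, T_eth = params$T_eth)
    st <- control_step(controller, measured, obs)
    controller <- st$controller
    U_raw <- st$U
    U <- clip_to(U_raw, 0, 100)
    clamped[k] <- abs(U_raw - U) > 1e-12
    cutoff[k] <- isTRUE(st$cutoff)
    controller$state$prev_speed <- U
    t_s[k] <- (k - 1) * dt; T_bulk[k] <- T; V_mL[k] <- V
    U_pct[k] <- U; dU_pct[k] <- st$dU; T_out[k] <- d0$T_out
    for (s in seq_len(n_sub)) {
      tv <- rk4_step(T, V, U, params$ode_dt, params, "fed_batch")
      T <- tv[1]; V <- tv[2]
    }
  }
  new_runlog(tibble(
    t_s = t_s, T_bulk_C = T_bulk, V_mL = V_mL, U_pct = U_pct, dU_pct = dU_pct,
    T_in_C = params$T_cool_in, T_out_C = T_out, T_eth_C = params$T_eth,
    clamped = clamped, cutoff = cutoff
  ), sample_dt = dt, setpoint = params$setpoint)
}

#' Run a pseudosteady reaction-curve experiment
#'
#' Emulates the open-loop step tests used to characterise the process: the
#' volume is held constant by exchanging prediluted extract at equal rates,
#' the system is brought to steady state at the nominal pump speed `U0`, a
#' step `dU` is applied, and integration continues until a new steady state.
#'
#' @param params Calibrated [plant_params()].
#' @param V_fixed Constant volume, mL (300, 450 or 600 in the published
#'   protocol; any value in range is accepted).
#' @param dU Pump-speed step, % (applied at t = 0 after the settling phase).
#' @param U0 Nominal pump speed, % (default from `params`).
#' @param max_horizon Maximum integration time per phase, s.
#' @param ss_tol Steady-state criterion: max |dT/dt| over a trailing 60 s
#'   window, degC/s.
#' @return A `runlog` tibble; the pre-step settling phase has t < 0.
#' @export
run_pseudosteady <- function(params, V_fixed, dU, U0 = params$U0,
                             max_horizon = 20000, ss_tol = 1e-7) {
  need_calibration(params)
  dt <- params$sample_dt
  n_sub <- round(dt / params$ode_dt)
  integrate_phase <- function(T_start, U, t_offset) {
    T <- T_start
    keep <- list(); k <- 0
    window <- max(round(60 / dt), 2)
    repeat {
      k <- k + 1
      t <- t_offset + (k - 1) * dt
      d <- plant_derivatives(list(T_bulk = T, V = V_fixed), U, params, "pseudosteady")
      keep[[k]] <- c(t, T, U, d$dT, d$T_out)
      if (k * dt > max_horizon) {
        abort("pseudosteady run did not reach steady state within max_horizon",
              class = "precool_convergence_error")
      }
      if (k > window) {
        recent <- vapply(keep[(k - window):k], `[`, numeric(1), 4)
        if (max(abs(recent)) < ss_tol) break
      }
      for (s in seq_len(n_sub)) {
        T <- rk4_step(T, V_fixed, U, params$ode_dt, params, "pseudosteady")[1]
      }
    }
    m <- do.call(rbind, keep)
    list(T_end = m[nrow(m), 2], m = m)
  }
  ph1 <- integrate_phase(params$setpoint, U0, t_offset = -max_horizon)
  ph1$m[, 1] <- ph1$m[, 1] - ph1$m[nrow(ph1$m), 1] - dt   # end just before 0
  U1 <- clip_to(U0 + dU, 0, 100)
  ph2 <- integrate_phase(ph1$T_end, U1, t_offset = 0)
  m <- rbind(ph1$m, ph2$m)
  new_runlog(tibble(
    t_s = m[, 1], T_bulk_C = m[, 2], V_mL = V_fixed, U_pct = m[, 3],
    dU_pct = c(0, diff(m[, 3])), T_in_C = params$T_cool_in, T_out_C = m[, 5],
    T_eth_C = params$T_eth, clamped = FALSE
  ), sample_dt = dt, setpoint = params$setpoint)
}

#' Static gain from a reaction curve
#'
#' \eqn{K_p = (T_{final} - T_{initial}) / |\Delta U|}, the reaction-curve
#' table convention: the sign records the direction of the temperature
#' response, so speeding the pump up yields a negative gain and slowing it
#' down a positive one.
#'
#' @param curve A `runlog` from [run_pseudosteady()]; the pre-step phase
#'   (t < 0) supplies the initial steady state.
#' @param dU The applied step, %.
#' @param ss_window Trailing window (s) over which the curve must be flat.
#' @param ss_tol Maximum temperature spread over the trailing window, degC.
#' @return The static gain, degC/%.
#' @export
estimate_static_gain <- function(curve, dU, ss_window = 60, ss_tol = 1e-4) {
  if (dU == 0) return(0)
  pre <- dplyr::filter(curve, .data$t_s < 0)
  post <- dplyr::filter(curve, .data$t_s >= 0)
  if (nrow(pre) == 0 || nrow(post) == 0) {
    abort("curve must contain a pre-step (t < 0) and post-step phase",
          class = "precool_config_error")
  }
  tail_T <- post$T_bulk_C[post$t_s >= max(post$t_s) - ss_window]
  if (diff(range(tail_T)) > ss_tol) {
    abort("reaction curve has not reached steady state", class = "precool_convergence_error")
  }
  (tail(post$T_bulk_C, 1) - tail(pre$T_bulk_C, 1)) / abs(dU)
}

#' Measure all six calibration gains by the step protocol
#'
#' Re-runs the full pseudosteady ODE protocol (settle at 40 %, step +-30 %,
#' settle again) at the three test volumes and estimates each static gain
#' from the simulated curves.
#'
#' @param params Calibrated [plant_params()].
#' @return [gain_targets()] with an extra `Kp_measured` column.
#' @export
measure_static_gains <- function(params) {
  tg <- gain_targets()
  tg$Kp_measured <- purrr::map2_dbl(tg$V_mL, tg$dU_pct, function(V, dU) {
    curve <- run_pseudosteady(params, V_fixed = V, dU = dU)
    estimate_static_gain(curve, dU)
  })
  tg
}
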