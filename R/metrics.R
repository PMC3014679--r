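#' Closed-loop performance indices
#'
#' Scalar indices used to score and compare controllers on a batch run. All
#' take a run log and the temperature set point and are defined so that
#' smaller is better.
#'
#' * `overshoot()`: maximum upward excursion `max(0, max(T - setpoint))`,
#'   degC. The excursion in this process is upward: ethanol dissolution heats
#'   the bulk early in the batch while the transfer area is still small.
#' * `itae()`: integral of time-weighted absolute error
#'   \eqn{\int t\,|T - T_{sp}|\,dt} (trapezoidal), degC s^2.
#' * `rise_and_response_time()`: the rise time is the first time the
#'   temperature re-crosses the set point from above after the initial
#'   excursion (0 if the trace never leaves the settling band upward); the
#'   response time is
#'   the last-exit time of the `+- band` settling band (the first time after
#'   which the error stays within the band for the rest of the run). A run
#'   that never settles gets the batch duration and `settled = FALSE`.
#' * `saturation_time()`: total time spent with the pump saturated at 0 or
#'   100 %, sample-weighted, s. Samples where a predictive controller's
#'   low-temperature cutoff forced the pump off (a `cutoff` column in the
#'   log) can be excluded.
#' * `energy_proxy()`: pump-affinity electric energy
#'   \eqn{\int P_{max} (U/100)^3 dt} in kWh. A proxy for relative
#'   consumption between controllers, not a metered plant figure.
#'
#' @param log A run-log tibble (see [run_fed_batch()]).
#' @param setpoint Set point, degC (defaults to the value stored in the log).
#' @param band Settling band, degC (default 0.2).
#' @param exclude_cutoff If `TRUE`, pump-off samples flagged in a `cutoff`
#'   column do not count as saturation.
#' @param P_max Pump motor power at 100 %, kW.
#' @return A scalar (a two-element list for `rise_and_response_time()`).
#' @name performance_indices
NULL

log_setpoint <- function(log, setpoint) {
  if (!is.null(setpoint) && is.finite(setpoint)) return(setpoint)
  sp <- attr(log, "setpoint")
  if (is.null(sp) || !is.finite(sp)) {
    abort("no setpoint stored in log; pass `setpoint`", class = "precool_config_error")
  }
  sp
}

#' @rdname performance_indices
#' @export
overshoot <- function(log, setpoint = NULL) {
  sp <- log_setpoint(log, setpoint)
  max(0, max(log$T_bulk_C - sp))
}

#' @rdname performance_indices
#' @export
itae <- function(log, setpoint = NULL) {
  sp <- log_setpoint(log, setpoint)
  t <- log$t_s - log$t_s[1]
  f <- t * abs(log$T_bulk_C - sp)
  sum((head(f, -1) + tail(f, -1)) / 2 * diff(t))
}

#' @rdname performance_indices
#' @export
rise_and_response_time <- function(log, setpoint = NULL, band = 0.2) {
  stopifnot(band > 0)
  sp <- log_setpoint(log, setpoint)
  t <- log$t_s - log$t_s[1]
  e <- log$T_bulk_C - sp
  ## an initial excursion only counts once it leaves the settling band
  above <- which(e > band)
  if (length(above) == 0) {
    rise <- 0
  } else {
    back <- which(e <= 0 & seq_along(e) > above[1])
    rise <- if (length(back) == 0) tail(t, 1) else t[back[1]]
  }
  out <- which(abs(e) > band)
  if (length(out) == 0) {
    resp <- 0; settled <- TRUE
  } else if (tail(out, 1) == length(e)) {
    resp <- tail(t, 1); settled <- FALSE
  } else {
    resp <- t[tail(out, 1) + 1]; settled <- TRUE
  }
  list(rise_time = rise, response_time = resp, settled = settled)
}

#' @rdname performance_indices
#' @export
saturation_time <- function(log, exclude_cutoff = FALSE) {
  dt <- diff(log$t_s)
  dt <- c(dt, tail(dt, 1))
  sat <- log$U_pct <= 1e-9 | log$U_pct >= 100 - 1e-9
  if (exclude_cutoff && "cutoff" %in% names(log)) {
    sat <- sat & !(log$cutoff & log$U_pct <= 1e-9)
  }
  sum(dt[sat])
}

#' @rdname performance_indices
#' @export
energy_proxy <- function(log, P_max = 0.75) {
  p <- P_max * (log$U_pct / 100)^3            # kW
  sum((head(p, -1) + tail(p, -1)) / 2 * diff(log$t_s)) / 3600   # kWh
}

#' Performance report for one run
#'
#' Bundles all indices of [performance_indices] for a single closed-loop (or
#' open-loop) run into one tidy row.
#'
#' @inheritParams performance_indices
#' @param controller_name Label for the controller that produced the run.
#' @return A one-row tibble of class `performance_report`: `controller`,
#'   `overshoot_C`, `rise_time_s`, `response_time_s`, `itae_C_s2`,
#'   `saturation_time_s`, `energy_kWh`, `settled`.
#' @export
performance_report <- function(log, controller_name = "controller",
                               setpoint = NULL, band = 0.2,
                               exclude_cutoff = FALSE, P_max = 0.75) {
  rt <- rise_and_response_time(log, setpoint, band)
  out <- tibble(
    controller = controller_name,
    overshoot_C = overshoot(log, setpoint),
    rise_time_s = rt$rise_time,
    response_time_s = rt$response_time,
    itae_C_s2 = itae(log, setpoint),
    saturation_time_s = saturation_time(log, exclude_cutoff),
    energy_kWh = energy_proxy(log, P_max),
    settled = rt$settled
  )
  class(out) <- c("performance_report", class(out))
  out
}

#' Rank controllers on their performance reports
#'
#' Stacks several [performance_report()] rows and adds per-metric ranks
#' (rank 1 = best = smallest; ties share the minimum rank).
#'
#' @param reports A list of reports, or a tibble of stacked report rows
#'   (>= 2 rows).
#' @return A tibble with the report columns plus `rank_<metric>` columns.
#' @export
compare_controllers <- function(reports) {
  if (is.list(reports) && !is.data.frame(reports)) reports <- dplyr::bind_rows(reports)
  if (nrow(reports) < 2) abort("need at least two reports", class = "precool_config_error")
  metrics <- c("overshoot_C", "rise_time_s", "response_time_s", "itae_C_s2",
               "saturation_time_s", "energy_kWh")
  for (m in metrics) {
    reports[[paste0("rank_", m)]] <- rank(reports[[m]], ties.method = "min")
  }
  reports
}
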