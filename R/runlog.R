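## run-log tibble: uniformly sampled closed- or open-loop time series

runlog_cols <- c("t_s", "T_bulk_C", "V_mL", "U_pct", "dU_pct",
                 "T_in_C", "T_out_C", "T_eth_C")

new_runlog <- function(df, sample_dt, setpoint) {
  stopifnot(all(runlog_cols %in% names(df)))
  structure(as_tibble(df), class = c("runlog", class(as_tibble(df))),
            sample_dt = sample_dt, setpoint = setpoint)
}

#' Validate a run log
#'
#' Checks the invariants every run log must satisfy: the fixed column set,
#' strictly increasing uniformly spaced time, and pump speed within
#' `[0, 100]` %.
#'
#' @param log A run-log tibble.
#' @return `log`, invisibly; aborts with a descriptive error otherwise.
#' @export
validate_runlog <- function(log) {
  missing <- setdiff(runlog_cols, names(log))
  if (length(missing) > 0) {
    abort(paste("run log lacks columns:", paste(missing, collapse = ", ")),
          class = "precool_config_error")
  }
  dt <- diff(log$t_s)
  if (any(dt <= 0) || diff(range(dt)) > 1e-9) {
    abort("run log time must be strictly increasing with constant spacing",
          class = "precool_config_error")
  }
  if (any(log$U_pct < -1e-9 | log$U_pct > 100 + 1e-9)) {
    abort("pump speed outside [0, 100] %", class = "precool_config_error")
  }
  invisible(log)
}

#' Write / read a run log as CSV
#'
#' The on-disk format is the fixed eight-column CSV (`t_s, T_bulk_C, V_mL,
#' U_pct, dU_pct, T_in_C, T_out_C, T_eth_C`); auxiliary in-memory columns are
#' dropped on write.
#'
#' @param log A run-log tibble.
#' @param path File path.
#' @return `write_runlog()` returns `path` invisibly; `read_runlog()` the
#'   tibble.
#' @export
write_runlog <- function(log, path) {
  readr::write_csv(log[runlog_cols], path)
  invisible(path)
}

#' @rdname write_runlog
#' @export
read_runlog <- function(path) {
  df <- readr::read_csv(path, show_col_types = FALSE)
  validate_runlog(df)
  dt <- df$t_s[2] - df$t_s[1]
  new_runlog(df, sample_dt = dt, setpoint = NA_real_)
}

#' Plot a run log
#'
#' Two stacked panels: bulk temperature against the set point, and pump
#' speed.
#'
#' @param object A run-log tibble.
#' @param setpoint Set point to draw, degC (defaults to the attribute stored
#'   in the log).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.runlog <- function(object, setpoint = attr(object, "setpoint"), ...) {
  long <- object |>
    select("t_s", "T_bulk_C", "U_pct") |>
    tidyr::pivot_longer(-"t_s", names_to = "signal") |>
    mutate(signal = dplyr::recode(.data$signal,
                                  T_bulk_C = "bulk temperature (°C)",
                                  U_pct = "pump speed (%)"))
  gg <- ggplot2::ggplot(long, ggplot2::aes(.data$t_s, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~signal, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (s)", y = NULL) +
    ggplot2::theme_minimal()
  if (!is.null(setpoint) && is.finite(setpoint)) {
    gg <- gg + ggplot2::geom_hline(
      data = tibble(signal = "bulk temperature (°C)", y = setpoint),
      ggplot2::aes(yintercept = .data$y), linetype = 2, colour = "grey40")
  }
  gg
}
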