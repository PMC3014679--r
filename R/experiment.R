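#' Experiment configuration
#'
#' Reproducible-experiment plumbing: a single YAML document describes the
#' plant overrides, controller settings and seeds of an experiment; it is
#' schema-checked on load and echoed verbatim into every output directory so
#' a result can always be traced to the exact configuration that produced
#' it.
#'
#' @param path YAML file; `default_config()` returns the built-in defaults.
#' @return A named list of class `experiment_config`.
#' @export
read_experiment_config <- function(path) {
  cfg <- yaml::read_yaml(path)
  validate_config(modifyList(default_config(), cfg))
}

#' @rdname read_experiment_config
#' @export
default_config <- function() {
  validate_config(list(
    plant = list(),               # overrides for plant_params()
    duration = 1200,
    band = 0.2,
    seed = 1L,
    fuzzy = list(n_grid = 10001L, U0 = 40),
    anfis = list(epochs = 100L, lr = 0.01, T0 = c(3.5, 5, 6.5, 8)),
    mpc = list(max_step = 35, cutoff_T = 4.9, n_staircase = 6L,
               closed_T0 = c(5, 7)),
    out_dir = NULL
  ))
}

validate_config <- function(cfg) {
  required <- c("plant", "duration", "band", "seed", "fuzzy", "anfis", "mpc")
  missing <- setdiff(required, names(cfg))
  if (length(missing) > 0) {
    abort(paste("config lacks fields:", paste(missing, collapse = ", ")),
          class = "precool_config_error")
  }
  if (!is.numeric(cfg$seed) || length(cfg$seed) != 1) {
    abort("config seed must be a single integer", class = "precool_config_error")
  }
  bad <- setdiff(names(cfg$plant), names(formals(plant_params)))
  if (length(bad) > 0) {
    abort(paste("unknown plant parameters:", paste(bad, collapse = ", ")),
          class = "precool_config_error")
  }
  structure(cfg, class = "experiment_config")
}

config_plant <- function(cfg) {
  do.call(default_plant, cfg$plant)
}

echo_config <- function(cfg, out_dir) {
  if (is.null(out_dir)) return(invisible(NULL))
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  yaml::write_yaml(unclass(cfg), file.path(out_dir, "config.yaml"))
  invisible(out_dir)
}

#' Calibrate the plant from a configuration
#'
#' Runs [calibrate_plant()] under the configured plant overrides and, when an
#' output directory is set, writes the per-volume parameters and gain
#' residuals.
#'
#' @param cfg An `experiment_config`.
#' @return The calibrated [plant_params()], invisibly returning its residual
#'   table as attribute output files where configured.
#' @export
cmd_calibrate <- function(cfg = default_config()) {
  plant <- config_plant(cfg)
  if (!is.null(cfg$out_dir)) {
    echo_config(cfg, cfg$out_dir)
    readr::write_csv(tidy(plant$calibration),
                     file.path(cfg$out_dir, "calibration.csv"))
    readr::write_csv(plant$calibration$residuals,
                     file.path(cfg$out_dir, "calibration_residuals.csv"))
  }
  plant
}

#' Build one of the package's controllers by name
#'
#' @param name One of `"fuzzy-original"`, `"fuzzy-tuned"`, `"anfis3"`,
#'   `"anfis4"`, `"mpc"`, `"open-loop"`.
#' @param cfg An `experiment_config`.
#' @param plant Calibrated plant (built from `cfg` when omitted).
#' @param models Optional pre-trained models (list with `anfis3`, `anfis4`,
#'   `mlp`) to avoid retraining.
#' @return A controller object.
#' @export
build_controller <- function(name, cfg = default_config(), plant = NULL,
                             models = NULL) {
  if (is.null(plant)) plant <- config_plant(cfg)
  U0 <- cfg$fuzzy$U0
  switch(
    name,
    "fuzzy-original" = fuzzy_pi("original", setpoint = plant$setpoint,
                                n_grid = cfg$fuzzy$n_grid, U0 = U0),
    "fuzzy-tuned" = fuzzy_pi("tuned", setpoint = plant$setpoint,
                             n_grid = cfg$fuzzy$n_grid, U0 = U0),
    "anfis3" = as_controller(models$anfis3 %||% cmd_train(cfg, "anfis3", plant), U0 = U0),
    "anfis4" = as_controller(models$anfis4 %||% cmd_train(cfg, "anfis4", plant), U0 = U0),
    "mpc" = mpc_controller(models$mlp %||% cmd_train(cfg, "ann", plant),
                           mpc_constraints(max_step = cfg$mpc$max_step,
                                           cutoff_T = cfg$mpc$cutoff_T,
                                           setpoint = plant$setpoint),
                           U0 = U0),
    "open-loop" = constant_controller(U0),
    abort(sprintf("unknown controller '%s'", name), class = "precool_usage_error")
  )
}

#' Train a model from a configuration
#'
#' `which = "anfis3"` / `"anfis4"` trains the Takagi-Sugeno mimic of the
#' tuned fuzzy-PI controller on the closed-loop database; `"ann"` trains the
#' one-step-ahead neural model on the staircase/closed-loop run collection.
#' Randomness is funneled through `cfg$seed`.
#'
#' @inheritParams build_controller
#' @param which `"anfis3"`, `"anfis4"` or `"ann"`.
#' @return The trained model; serialized to JSON under `cfg$out_dir` when
#'   set.
#' @export
cmd_train <- function(cfg = default_config(), which = c("anfis3", "anfis4", "ann"),
                      plant = NULL) {
  which <- match.arg(which)
  if (is.null(plant)) plant <- config_plant(cfg)
  set.seed(cfg$seed)
  if (which %in% c("anfis3", "anfis4")) {
    teacher <- fuzzy_pi("tuned", setpoint = plant$setpoint, n_grid = cfg$fuzzy$n_grid,
                        U0 = cfg$fuzzy$U0)
    data <- anfis_dataset(teacher, plant, T0 = cfg$anfis$T0,
                          duration = cfg$duration)
    model <- anfis_train(ts_model(if (which == "anfis3") 3L else 4L,
                                  setpoint = plant$setpoint),
                         data, epochs = cfg$anfis$epochs, lr = cfg$anfis$lr)
    report <- glance(model)
    report$test_rmse <- ts_rmse(model, data)
    if (!is.null(cfg$out_dir)) {
      echo_config(cfg, cfg$out_dir)
      ts_write_json(model, file.path(cfg$out_dir, paste0(which, ".json")))
      jsonlite::write_json(report, file.path(cfg$out_dir, paste0(which, "_report.json")),
                           digits = NA, auto_unbox = TRUE)
    }
    model
  } else {
    runs <- mpc_training_runs(plant, seed = cfg$seed,
                              n_staircase = cfg$mpc$n_staircase,
                              closed_T0 = cfg$mpc$closed_T0,
                              duration = cfg$duration)
    data <- build_training_data(runs)
    model <- mlp_train(mlp_model(seed = cfg$seed), data)
    report <- dplyr::bind_cols(glance(model), dispersion_stats(model, data))
    if (!is.null(cfg$out_dir)) {
      echo_config(cfg, cfg$out_dir)
      mlp_write_json(model, file.path(cfg$out_dir, "ann.json"))
      jsonlite::write_json(report, file.path(cfg$out_dir, "ann_report.json"),
                           digits = NA, auto_unbox = TRUE)
    }
    model
  }
}

#' Run one closed-loop experiment end-to-end
#'
#' Builds the plant and the named controller, runs a fed-batch, and scores
#' it. Deterministic given the configuration seed.
#'
#' @inheritParams build_controller
#' @return A list: `log` (run log) and `report` ([performance_report()]);
#'   written to `runlog_<name>.csv` and `report_<name>.json` under
#'   `cfg$out_dir` when set.
#' @export
cmd_run <- function(cfg = default_config(), name = "fuzzy-tuned", models = NULL) {
  plant <- config_plant(cfg)
  set.seed(cfg$seed)
  ctrl <- build_controller(name, cfg, plant, models)
  log <- run_fed_batch(ctrl, plant, duration = cfg$duration)
  report <- performance_report(log, controller_name = name, band = cfg$band,
                               P_max = plant$P_max)
  if (!is.null(cfg$out_dir)) {
    echo_config(cfg, cfg$out_dir)
    write_runlog(log, file.path(cfg$out_dir, paste0("runlog_", name, ".csv")))
    jsonlite::write_json(as.list(report), file.path(cfg$out_dir, paste0("report_", name, ".json")),
                         digits = NA, auto_unbox = TRUE)
  }
  list(log = log, report = report)
}

#' Run and rank all controllers
#'
#' Trains what needs training, runs the five controller configurations plus
#' the open-loop baseline under identical conditions, and returns the ranked
#' comparison table.
#'
#' @inheritParams build_controller
#' @param names Controllers to include.
#' @return A list: `reports` (ranked tibble from [compare_controllers()])
#'   and `logs` (named list of run logs).
#' @export
cmd_compare <- function(cfg = default_config(),
                        names = c("fuzzy-tuned", "anfis3", "anfis4", "mpc",
                                  "open-loop")) {
  plant <- config_plant(cfg)
  models <- list()
  if (any(c("anfis3", "anfis4", "mpc") %in% names)) {
    if ("anfis3" %in% names) models$anfis3 <- cmd_train(cfg, "anfis3", plant)
    if ("anfis4" %in% names) models$anfis4 <- cmd_train(cfg, "anfis4", plant)
    if ("mpc" %in% names) models$mlp <- cmd_train(cfg, "ann", plant)
  }
  logs <- list(); reports <- list()
  for (nm in names) {
    set.seed(cfg$seed)
    ctrl <- build_controller(nm, cfg, plant, models)
    logs[[nm]] <- run_fed_batch(ctrl, plant, duration = cfg$duration)
    reports[[nm]] <- performance_report(logs[[nm]], controller_name = nm,
                                        band = cfg$band, P_max = plant$P_max)
  }
  tab <- compare_controllers(reports)
  if (!is.null(cfg$out_dir)) {
    echo_config(cfg, cfg$out_dir)
    readr::write_csv(tab, file.path(cfg$out_dir, "comparison.csv"))
  }
  list(reports = tab, logs = logs)
}
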