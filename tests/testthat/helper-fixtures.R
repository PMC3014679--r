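## Shared heavy fixtures, built once per test session and cached. Everything
## is generated in code; nothing is read from disk.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (!exists(name, envir = .fixtures)) {
    assign(name, build(), envir = .fixtures)
  }
  get(name, envir = .fixtures)
}

fx_plant <- function() fixture("plant", function() default_plant())

fx_teacher <- function() fixture("teacher", function() fuzzy_pi("tuned"))

fx_anfis_data <- function() {
  fixture("anfis_data", function() {
    anfis_dataset(fx_teacher(), fx_plant())
  })
}

fx_anfis3 <- function() {
  fixture("anfis3", function() {
    suppressWarnings(anfis_train(ts_model(3), fx_anfis_data(), epochs = 100))
  })
}

fx_anfis4 <- function() {
  fixture("anfis4", function() {
    suppressWarnings(anfis_train(ts_model(4), fx_anfis_data(), epochs = 100))
  })
}

fx_mlp_data <- function() {
  fixture("mlp_data", function() {
    build_training_data(mpc_training_runs(fx_plant(), seed = 1))
  })
}

fx_mlp <- function() {
  fixture("mlp", function() mlp_train(mlp_model(seed = 1), fx_mlp_data()))
}

## closed-loop run logs for the comparison-based checks
fx_logs <- function() {
  fixture("logs", function() {
    plant <- fx_plant()
    ctrls <- list(
      "fuzzy-tuned" = fuzzy_pi("tuned"),
      "anfis3" = as_controller(fx_anfis3()),
      "anfis4" = as_controller(fx_anfis4()),
      "mpc" = mpc_controller(fx_mlp()),
      "open-loop" = constant_controller(40)
    )
    lapply(ctrls, run_fed_batch, params = plant, duration = 1200)
  })
}
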