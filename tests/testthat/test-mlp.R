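test_that("supervised pairs align features at k with the temperature at k+1", {
  plant <- fx_plant()
  log <- run_fed_batch(constant_controller(40), plant, duration = 1000)
  expect_equal(nrow(log), 250)
  data <- build_training_data(list(log))
  expect_equal(nrow(data$X), 249)                  # one 1000-s batch -> 249 pairs
  ## no leakage: target is the *next* sample's bulk temperature
  expect_equal(data$y, log$T_bulk_C[-1])
  expect_equal(unname(data$X[, "T_bulk"]), log$T_bulk_C[-250])
  expect_equal(unname(data$X[, "L"]), log$V_mL[-250])
  expect_equal(colnames(data$X), mlp_features())

  ## runs with different sampling are rejected
  log2 <- log; log2$t_s <- log2$t_s * 2
  expect_error(build_training_data(list(log, log2)), class = "precool_config_error")
})

test_that("the 75/25 split is contiguous by run and honours run roles", {
  plant <- fx_plant()
  logs <- lapply(c(30, 50, 70, 90), function(U) {
    run_fed_batch(constant_controller(U), plant, duration = 200)
  })
  data <- build_training_data(logs)
  expect_equal(unique(data$role[data$run <= 3]), "train")
  expect_equal(unique(data$role[data$run == 4]), "test")
  ## roles attached to runs win over the default split
  attr(logs[[1]], "role") <- "test"
  data <- build_training_data(logs)
  expect_equal(unique(data$role[data$run == 1]), "test")
})

test_that("min-max scaling round-trips, with constant features pinned to zero", {
  X <- cbind(a = c(1, 2, 3), b = c(5, 5, 5), c = c(-2, 0, 2))
  y <- c(10, 20, 30)
  s <- precool:::scale_fit(X, y)
  Xs <- precool:::scale_x(X, s)
  expect_equal(range(Xs[, "a"]), c(-1, 1))
  expect_equal(unname(Xs[, "b"]), c(0, 0, 0))      # constant feature
  expect_equal(precool:::unscale_y(precool:::scale_y(y, s), s), y)
})

test_that("the forward pass matches scalar arithmetic and is pure", {
  m <- mlp_model(seed = 3)
  m$scaling <- list(x_min = c(23, 0, 0, 0, 150, -35, 0),
                    x_max = c(23, 0, 2, 100, 750, 35, 12),
                    y_min = 0, y_max = 12)
  x <- c(23, 0, 0.4, 55, 420, -3, 6.2)
  X <- matrix(x, 1, dimnames = list(NULL, mlp_features()))
  expect_equal(mlp_predict(m, X), oracle_mlp_forward(m, x), tolerance = 1e-12)
  expect_equal(mlp_predict(m, X), mlp_predict(m, X))   # purity

  ## zero weights: prediction is the unscaled output bias
  z <- m
  z$W1[] <- 0; z$b1[] <- 0; z$W2[] <- 0; z$b2 <- 0.25
  expect_equal(mlp_predict(z, X),
               precool:::unscale_y(0.25, m$scaling), tolerance = 1e-12)

  expect_warning(mlp_predict(m, X * 100, warn_range = TRUE))
  expect_error(mlp_predict(mlp_model(), X), class = "precool_config_error")
})

test_that("Levenberg-Marquardt drives a noise-free target to near-zero error", {
  set.seed(11)
  n <- 400
  X <- cbind(T_alc = 23, T_in = 0, T_out = runif(n, 0, 1),
             U = runif(n, 0, 100), L = runif(n, 150, 750),
             dU = runif(n, -35, 35), T_bulk = runif(n, 4, 9))
  y <- 5 + 0.02 * X[, "U"] - 0.003 * X[, "L"] + 0.5 * X[, "T_bulk"]
  data <- list(X = X, y = y, run = rep(1:4, each = 100),
               role = rep(c("train", "test"), c(300, 100)))
  m <- mlp_train(mlp_model(seed = 2), data, max_rounds = 12)
  expect_lt(min(m$history$test_mse), 1e-6)
})

test_that("the neural model is adequate on held-out closed-loop runs (dispersion)", {
  disp <- dispersion_stats(fx_mlp(), fx_mlp_data())
  expect_gte(disp$slope, 0.95)
  expect_lte(disp$slope, 1.05)
  expect_gte(disp$intercept, -0.1)
  expect_lte(disp$intercept, 0.1)
})

test_that("a permuted-target control shows no spurious skill", {
  data <- fx_mlp_data()
  set.seed(99)
  shuffled <- data
  shuffled$y <- sample(data$y)
  m <- tryCatch(
    mlp_train(mlp_model(seed = 5), shuffled, max_rounds = 3, patience = 1),
    error = function(e) NULL                        # divergence is acceptable
  )
  if (!is.null(m)) {
    disp <- dispersion_stats(m, shuffled)
    expect_lt(abs(disp$slope), 0.3)
  } else {
    succeed("training on permuted targets diverged, as expected")
  }
})

test_that("JSON serialization round-trips the network", {
  m <- fx_mlp()
  path <- withr::local_tempfile(fileext = ".json")
  mlp_write_json(m, path)
  back <- mlp_read_json(path)
  X <- fx_mlp_data()$X[1:20, ]
  expect_equal(mlp_predict(back, X), mlp_predict(m, X), tolerance = 1e-12)
})

test_that("the low-temperature cutoff overrides the optimizer", {
  obs <- tibble::tibble(T_bulk = 4.8, V = 400, T_out = 0.2, T_in = 0, T_eth = 23)
  st <- mpc_step(fx_mlp(), obs, U_prev = 60)
  expect_equal(st$U, 0)
  expect_true(st$cutoff)
})

test_that("a monotone objective drives the solver to the interval boundary", {
  f <- function(U) 2 + 0.1 * U            # strictly increasing
  expect_equal(precool:::solve_bounded_scalar(f, 20, 70, prefer = 45), 20,
               tolerance = 1e-6)
  g <- function(U) 2 - 0.1 * U            # strictly decreasing
  expect_equal(precool:::solve_bounded_scalar(g, 20, 70, prefer = 45), 70,
               tolerance = 1e-6)
  ## flat objective: ties break toward the preferred value
  expect_equal(precool:::solve_bounded_scalar(function(U) 1, 20, 70, prefer = 45),
               45, tolerance = 1e-6)
})

test_that("the solver agrees with a 0.01 % grid search on random instances", {
  m <- fx_mlp()
  cn <- mpc_constraints()
  set.seed(17)
  worst <- 0
  for (i in 1:100) {
    obs <- tibble::tibble(T_bulk = runif(1, 4.95, 9), V = runif(1, 150, 750),
                          T_out = runif(1, 0, 1), T_in = 0, T_eth = 23)
    U_prev <- runif(1, 0, 100)
    st <- mpc_step(m, obs, U_prev, cn)
    f <- precool:::mpc_objective(m, obs, U_prev, cn)
    grid <- seq(st$lb, st$ub, by = 0.01)
    fg <- f(grid)                       # objective is row-vectorized in U
    U_grid <- grid[which.min(fg)]
    ## compare by objective value (ties in U are legitimate)
    expect_lte(f(st$U), min(fg) + 1e-8)
    worst <- max(worst, abs(st$U - U_grid))
    expect_true(st$U >= st$lb - 1e-9 && st$U <= st$ub + 1e-9)
  }
  expect_lt(worst, 0.05)
})

test_that("every closed-loop MPC action is feasible", {
  log <- fx_logs()[["mpc"]]
  cn <- mpc_constraints()
  expect_true(all(log$U_pct >= cn$U_min - 1e-9))
  expect_true(all(log$U_pct <= cn$U_max + 1e-9))
  steps <- abs(diff(log$U_pct))
  expect_true(all(steps <= cn$max_step + 1e-9))
  ## the pump is off whenever the bulk is at or below the cutoff
  cold <- log$T_bulk_C <= cn$cutoff_T
  expect_true(all(log$U_pct[cold] == 0))
  ## and the loop holds the set point after the initial excursion
  rt <- rise_and_response_time(log, setpoint = 5, band = 0.5)
  expect_true(rt$settled)
  late <- log$T_bulk_C[log$t_s > rt$response_time]
  expect_true(all(abs(late - 5) <= 0.5))
})
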