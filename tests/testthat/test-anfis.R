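test_that("the grid database enumerates row-major with the 1-based odd/even split", {
  data <- anfis_dataset_grid(fx_teacher(), grid_n = 21)
  expect_equal(nrow(data), 441)
  expect_equal(sum(data$split == "train"), 221)       # odd indices
  expect_equal(sum(data$split == "validation"), 220)  # even indices
  expect_equal(data$split[1], "train")
  ## eps varies slowest
  expect_equal(data$eps[1:21], rep(-1, 21))
  ## every target is the teacher's own action
  idx <- c(1, 117, 221, 441)
  for (i in idx) {
    expect_equal(data$target[i],
                 evaluate_action(fx_teacher(), data$eps[i], data$deps[i]))
  }
  expect_error(anfis_dataset_grid(fx_teacher(), grid_n = 11),
               class = "precool_config_error")
})

test_that("the closed-loop database stays inside the universes and on-policy", {
  data <- fx_anfis_data()
  expect_equal(nrow(data), 4 * 300)                  # 4 batches x 1200 s / 4 s
  expect_true(all(data$eps >= -1 & data$eps <= 1))
  expect_true(all(data$deps >= -0.5 & data$deps <= 0.5))
  ## closed-loop operation concentrates on zero-to-positive errors
  expect_gt(mean(data$eps >= 0), 0.9)
  ## spot-check targets against the teacher
  for (i in c(2, 500, 999)) {
    expect_equal(data$target[i],
                 evaluate_action(fx_teacher(), data$eps[i], data$deps[i]))
  }
})

test_that("normalized firing strengths are a partition of unity and stay positive", {
  for (ne in c(3, 4)) {
    model <- ts_model(ne)
    set.seed(ne)
    eps <- runif(200, -1, 1); deps <- runif(200, -0.5, 0.5)
    W <- precool:::ts_firing(model, eps, deps)
    expect_equal(dim(W), c(200L, ne * 7L))
    expect_equal(rowSums(W), rep(1, 200), tolerance = 1e-12)
    expect_true(all(W >= 0))
  }
})

test_that("the forward pass is the normalized weighted average of linear consequents", {
  model <- ts_model(3)
  ## identical constant consequents collapse to that constant everywhere
  model$consequents[, "r"] <- 4.2
  set.seed(1)
  eps <- runif(50, -1, 1); deps <- runif(50, -0.5, 0.5)
  expect_equal(ts_forward(model, eps, deps), rep(4.2, 50), tolerance = 1e-12)

  ## single-rule region: both inputs at shoulder apexes
  model <- ts_model(3)
  model$consequents[] <- matrix(rnorm(63), 21, 3)
  k <- (3 - 1) * 7 + 1                # rule (PL, NL)
  expect_equal(ts_forward(model, 1, -0.5),
               unname(model$consequents[k, "p"] * 1 +
                      model$consequents[k, "q"] * -0.5 +
                      model$consequents[k, "r"]),
               tolerance = 1e-12)

  ## random models match the scalar-loop oracle
  for (ne in c(3, 4)) {
    m <- ts_model(ne)
    m$consequents[] <- matrix(rnorm(ne * 7 * 3, sd = 3), ne * 7, 3)
    for (i in 1:25) {
      e <- runif(1, -1.2, 1.2); d <- runif(1, -0.6, 0.6)
      expect_equal(ts_forward(m, e, d), oracle_ts_forward(m, e, d),
                   tolerance = 1e-10)
    }
  }
})

test_that("the forward map is continuous (jumps shrink linearly with the grid)", {
  model <- fx_anfis3()
  eps <- seq(-1, 1, length.out = 401)
  for (d in c(-0.3, 0, 0.25)) {
    f <- ts_forward(model, eps, rep(d, length(eps)))
    jump_c <- max(abs(diff(f)))
    f2 <- ts_forward(model, seq(-1, 1, length.out = 4001), rep(d, 4001))
    jump_f <- max(abs(diff(f2)))
    expect_lt(jump_f, jump_c / 5)     # ~10x finer grid, >=5x smaller jumps
  }
})

test_that("hybrid training recovers a known model and respects epochs = 0", {
  truth <- ts_model(3)
  set.seed(7)
  truth$consequents[] <- matrix(rnorm(63, sd = 2), 21, 3)
  grid <- tidyr::expand_grid(eps = seq(-1, 1, length.out = 25),
                             deps = seq(-0.5, 0.5, length.out = 25))
  data <- tibble::tibble(
    eps = grid$eps, deps = grid$deps,
    target = ts_forward(truth, grid$eps, grid$deps),
    split = ifelse(seq_len(nrow(grid)) %% 2 == 1, "train", "validation")
  )
  fit <- suppressWarnings(anfis_train(ts_model(3), data, epochs = 0))
  ## recovery up to the ridge used for the (collinear) shoulder columns
  expect_lt(ts_rmse(fit, data), 1e-3)
  expect_equal(fit$PE, ts_model(3)$PE)                # premises untouched
  expect_equal(fit$PD, ts_model(3)$PD)

  expect_error(anfis_train(ts_model(3), data[0, ]), class = "precool_config_error")
})

test_that("both trained variants mimic the tuned controller to under 1 % of the output span", {
  data <- fx_anfis_data()
  span <- 33                                          # [-20, 13] %
  rmse3 <- ts_rmse(fx_anfis3(), data)                 # test set = all samples
  rmse4 <- ts_rmse(fx_anfis4(), data)
  expect_lt(rmse3, 0.01 * span)
  expect_lt(rmse4, 0.01 * span)
  ## the extra membership function buys accuracy
  expect_lt(rmse4, rmse3)
})

test_that("the controller wrapper integrates increments like the fuzzy interface", {
  model <- fx_anfis3()
  ctrl <- as_controller(model, U0 = 40)
  ## a zero map holds the pump speed at steady state
  zero <- ts_model(3)
  zc <- as_controller(zero, U0 = 40)
  st <- control_step(zc, 5.0)
  expect_equal(st$U, 40)
  expect_equal(st$dU, 0)
  ## output is clamped to the speed-variation universe, speed to [0, 100]
  hot <- as_controller(model, U0 = 95)
  st <- control_step(hot, 9)                          # eps clipped to 1
  expect_lte(st$dU, 13)
  expect_lte(st$U, 100)
  st2 <- control_step(st$controller, 9)
  expect_lte(st2$U, 100)
})

test_that("the neurofuzzy loop recovers the set point after the dissolution excursion", {
  log <- fx_logs()[["anfis3"]]
  rt <- rise_and_response_time(log, setpoint = 5, band = 0.3)
  expect_true(rt$settled)
  late <- log$T_bulk_C[log$t_s > rt$response_time]
  expect_true(all(abs(late - 5) <= 0.3))
})

test_that("JSON serialization round-trips a trained model", {
  model <- fx_anfis3()
  path <- withr::local_tempfile(fileext = ".json")
  ts_write_json(model, path)
  back <- ts_read_json(path)
  set.seed(3)
  eps <- runif(50, -1, 1); deps <- runif(50, -0.5, 0.5)
  expect_equal(ts_forward(back, eps, deps), ts_forward(model, eps, deps),
               tolerance = 1e-12)
})
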