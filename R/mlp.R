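#' Feedforward neural model of the one-step-ahead bulk temperature
#'
#' A 7-input, single-hidden-layer feedforward network that predicts the bulk
#' temperature one sample (4 s) ahead. The inputs at sample k are the ethanol
#' temperature, coolant inlet and outlet temperatures, pump speed, liquid
#' volume (the "level", which encodes run time), pump speed variation and
#' current bulk temperature; the output is the bulk temperature at k+1. The
#' hidden layer has twice as many nodes as the input layer (14) with
#' hyperbolic-tangent activation; the output node is linear -- the regression
#' convention. Inputs and target are min-max scaled to `[-1, 1]` with the
#' scaling stored in the model; constant features map to 0 and are inverted
#' back to their constant.
#'
#' @param n_hidden Hidden nodes (default 14 = 2 x 7 inputs).
#' @param seed Seed for the weight initialization.
#' @return An object of class `mlp_model` with untrained weights.
#' @seealso [mlp_train()], [mlp_predict()], [build_training_data()]
#' @export
mlp_model <- function(n_hidden = 14L, seed = 1L) {
  n_in <- length(mlp_features())
  set.seed(seed)
  structure(list(
    W1 = matrix(runif(n_hidden * n_in, -0.5, 0.5), n_hidden, n_in),
    b1 = runif(n_hidden, -0.5, 0.5),
    W2 = matrix(runif(n_hidden, -0.5, 0.5), 1L, n_hidden),
    b2 = runif(1L, -0.5, 0.5),
    scaling = NULL, seed = seed, trained = FALSE, history = NULL
  ), class = "mlp_model")
}

#' Input-layer feature names
#'
#' @return Character vector naming the 7 network inputs, in order.
#' @export
mlp_features <- function() {
  c("T_alc", "T_in", "T_out", "U", "L", "dU", "T_bulk")
}

## min-max scaling helpers ---------------------------------------------------
scale_fit <- function(X, y) {
  list(x_min = apply(X, 2, min), x_max = apply(X, 2, max),
       y_min = min(y), y_max = max(y))
}
scale_x <- function(X, s) {
  rng <- s$x_max - s$x_min
  Xs <- sweep(X, 2, s$x_min)
  Xs <- sweep(Xs, 2, ifelse(rng > 0, rng, 1), "/") * 2 - 1
  Xs[, rng == 0] <- 0
  Xs
}
scale_y <- function(y, s) {
  if (s$y_max > s$y_min) 2 * (y - s$y_min) / (s$y_max - s$y_min) - 1 else 0 * y
}
unscale_y <- function(ys, s) {
  if (s$y_max > s$y_min) (ys + 1) / 2 * (s$y_max - s$y_min) + s$y_min
  else rep(s$y_min, length(ys))
}

#' Supervised pairs from simulated runs
#'
#' Aligns features at sample k with the bulk temperature at k+1 for a
#' collection of runs, and tags each run as training or test. The split is
#' contiguous by run, never row-shuffled: by default the first 75 % of the
#' runs train and the rest test; runs carrying a `role` attribute (as those
#' from [mpc_training_runs()]) keep it. All runs must share the same sample
#' spacing.
#'
#' @param runs List of run-log tibbles.
#' @param train_frac Fraction of runs assigned to training when no roles are
#'   attached.
#' @return A list: `X` (feature matrix), `y` (targets, degC), `run` (run id
#'   per row), `role` (`"train"`/`"test"` per row).
#' @export
build_training_data <- function(runs, train_frac = 0.75) {
  dts <- vapply(runs, function(r) r$t_s[2] - r$t_s[1], numeric(1))
  if (diff(range(dts)) > 1e-9) {
    abort("runs have unequal sample spacing", class = "precool_config_error")
  }
  roles <- vapply(seq_along(runs), function(i) {
    role <- attr(runs[[i]], "role")
    if (is.null(role)) if (i <= ceiling(train_frac * length(runs))) "train" else "test"
    else role
  }, character(1))
  pieces <- purrr::imap(runs, function(r, i) {
    n <- nrow(r)
    X <- cbind(T_alc = r$T_eth_C, T_in = r$T_in_C, T_out = r$T_out_C,
               U = r$U_pct, L = r$V_mL, dU = r$dU_pct, T_bulk = r$T_bulk_C)[-n, , drop = FALSE]
    list(X = X, y = r$T_bulk_C[-1], run = rep(i, n - 1), role = rep(roles[i], n - 1))
  })
  list(X = do.call(rbind, purrr::map(pieces, "X")),
       y = unlist(purrr::map(pieces, "y")),
       run = unlist(purrr::map(pieces, "run")),
       role = unlist(purrr::map(pieces, "role")))
}

## forward pass on scaled inputs: returns scaled prediction and hidden matrix
mlp_forward_scaled <- function(model, Xs) {
  H <- tanh(Xs %*% t(model$W1) + matrix(model$b1, nrow(Xs), length(model$b1), byrow = TRUE))
  list(yhat = drop(H %*% t(model$W2)) + model$b2, H = H)
}

#' Predict the one-step-ahead bulk temperature
#'
#' @param model A trained [mlp_model()].
#' @param X Feature matrix (columns [mlp_features()]) or one-row data frame.
#' @param warn_range Warn when features fall outside the training range
#'   (they are used as-is; the tanh layer saturates gracefully).
#' @return Numeric vector of predicted temperatures, degC.
#' @export
mlp_predict <- function(model, X, warn_range = FALSE) {
  if (is.data.frame(X)) X <- as.matrix(X[, mlp_features()])
  if (is.null(dim(X))) X <- matrix(X, nrow = 1, dimnames = list(NULL, mlp_features()))
  s <- model$scaling
  if (is.null(s)) abort("model has no scaling; train it first", class = "precool_config_error")
  if (warn_range) {
    out_lo <- sweep(X, 2, s$x_min, `<`)
    out_hi <- sweep(X, 2, s$x_max, `>`)
    if (any(out_lo | out_hi)) warn("features outside the training range")
  }
  unscale_y(mlp_forward_scaled(model, scale_x(X, s))$yhat, s)
}

## pack/unpack the 127 network parameters
mlp_pack <- function(m) c(as.vector(m$W1), m$b1, as.vector(m$W2), m$b2)
mlp_unpack <- function(m, p) {
  nh <- nrow(m$W1); ni <- ncol(m$W1)
  m$W1 <- matrix(p[seq_len(nh * ni)], nh, ni)
  p <- p[-seq_len(nh * ni)]
  m$b1 <- p[seq_len(nh)]; p <- p[-seq_len(nh)]
  m$W2 <- matrix(p[seq_len(nh)], 1L, nh); p <- p[-seq_len(nh)]
  m$b2 <- p[1]
  m
}

#' Train the neural model by Levenberg-Marquardt
#'
#' Minimizes the mean squared one-step prediction error on the training runs
#' with the Levenberg-Marquardt algorithm ([minpack.lm::nls.lm], analytic
#' Jacobian), in rounds of a few iterations with the held-out test MSE
#' monitored between rounds; training stops when the test MSE stops
#' improving and the best round's weights are kept. A diverged fit (test MSE
#' worse than predicting the mean) is retried with a fresh seed, up to 5
#' times.
#'
#' @param model A [mlp_model()].
#' @param data From [build_training_data()].
#' @param max_rounds,iter_per_round LM effort: at most
#'   `max_rounds * iter_per_round` iterations.
#' @param patience Rounds without test-MSE improvement before stopping.
#' @return The trained model; `$history` holds per-round train/test MSE.
#' @export
mlp_train <- function(model, data, max_rounds = 20L, iter_per_round = 10L,
                      patience = 3L) {
  tr <- data$role == "train"
  te <- data$role == "test"
  if (!any(te)) te <- tr
  s <- scale_fit(data$X[tr, , drop = FALSE], data$y[tr])
  Xtr <- scale_x(data$X[tr, , drop = FALSE], s); ytr <- scale_y(data$y[tr], s)
  Xte <- scale_x(data$X[te, , drop = FALSE], s); yte <- scale_y(data$y[te], s)
  nh <- nrow(model$W1); ni <- ncol(model$W1)
  resid_fn <- function(p, m) {
    m <- mlp_unpack(m, p)
    mlp_forward_scaled(m, Xtr)$yhat - ytr
  }
  jac_fn <- function(p, m) {
    m <- mlp_unpack(m, p)
    fw <- mlp_forward_scaled(m, Xtr)
    D <- (1 - fw$H^2) * matrix(m$W2, nrow(Xtr), nh, byrow = TRUE)  # n x nh
    J_W1 <- do.call(cbind, lapply(seq_len(ni), function(j) D * Xtr[, j]))
    cbind(J_W1, D, fw$H, 1)
  }
  ## column order of jac must match mlp_pack: W1 (by column), b1, W2, b2 --
  ## J_W1 above is d/dW1[i,j] blocked by j which is exactly column-major W1.
  attempt <- function(seed) {
    m <- mlp_model(n_hidden = nh, seed = seed)
    m$scaling <- s
    par <- mlp_pack(m)
    best_par <- par; best_mse <- Inf; bad <- 0L
    hist <- list()
    for (round in seq_len(max_rounds)) {
      ## low per-round maxiter is deliberate (test-MSE monitoring between
      ## rounds); nls.lm warns about it, so silence just that
      fit <- suppressWarnings(
        minpack.lm::nls.lm(par, fn = resid_fn, jac = jac_fn, m = m,
                           control = minpack.lm::nls.lm.control(
                             maxiter = iter_per_round, ptol = 1e-12,
                             ftol = 1e-12, gtol = 1e-12)))
      par <- fit$par
      mse_tr <- mean(fit$fvec^2)
      mte <- mean((mlp_forward_scaled(mlp_unpack(m, par), Xte)$yhat - yte)^2)
      hist[[round]] <- tibble(round = round, train_mse = mse_tr, test_mse = mte)
      if (mte < best_mse - 1e-12) { best_mse <- mte; best_par <- par; bad <- 0L }
      else bad <- bad + 1L
      if (bad >= patience) break
    }
    m <- mlp_unpack(m, best_par)
    m$scaling <- s
    m$trained <- TRUE
    m$seed <- seed
    m$history <- dplyr::bind_rows(hist)
    m
  }
  base_mse <- mean((yte - mean(ytr))^2)
  for (k in 0:4) {
    m <- attempt(model$seed + k)
    if (min(m$history$test_mse) < base_mse) return(m)
  }
  abort("neural model training diverged for 5 seeds", class = "precool_training_error")
}

#' Dispersion statistics of the neural model on held-out data
#'
#' The standard adequacy check: regress predictions on targets for the test
#' rows; a suitable model has slope close to 1 and intercept close to 0.
#'
#' @param model A trained [mlp_model()].
#' @param data From [build_training_data()].
#' @param role Which rows to use (default `"test"`).
#' @return A one-row tibble: `slope`, `intercept`, `r_squared`, `n`.
#' @export
dispersion_stats <- function(model, data, role = "test") {
  rows <- data$role == role
  pred <- mlp_predict(model, data$X[rows, , drop = FALSE])
  targ <- data$y[rows]
  fit <- lm(pred ~ targ)
  tibble(slope = unname(coef(fit)[2]), intercept = unname(coef(fit)[1]),
         r_squared = summary(fit)$r.squared, n = sum(rows))
}

#' Serialize a neural model to/from JSON
#'
#' @param model A trained [mlp_model()].
#' @param path File path.
#' @return `mlp_write_json()` returns `path` invisibly; `mlp_read_json()`
#'   the model.
#' @export
mlp_write_json <- function(model, path) {
  obj <- list(W1 = unname(model$W1), b1 = model$b1, W2 = unname(model$W2),
              b2 = model$b2, scaling = model$scaling, seed = model$seed,
              trained = model$trained)
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname mlp_write_json
#' @export
mlp_read_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  m <- mlp_model(n_hidden = length(obj$b1), seed = obj$seed)
  m$W1 <- matrix(unlist(obj$W1), length(obj$b1), length(mlp_features()))
  m$b1 <- obj$b1
  m$W2 <- matrix(unlist(obj$W2), 1L)
  m$b2 <- obj$b2
  m$scaling <- obj$scaling
  m$trained <- isTRUE(obj$trained)
  m
}

#' Tidy / glance methods for the neural model
#'
#' @param x An [mlp_model()].
#' @param ... Unused.
#' @return `tidy()`: long tibble of weights and biases; `glance()`: one row
#'   with layer sizes and final MSEs.
#' @export
tidy.mlp_model <- function(x, ...) {
  dplyr::bind_rows(
    tidyr::expand_grid(layer = "hidden", to = seq_len(nrow(x$W1)),
                       from = mlp_features()) |>
      mutate(weight = as.vector(t(x$W1))),
    tibble(layer = "hidden_bias", to = seq_len(nrow(x$W1)), from = NA,
           weight = x$b1),
    tibble(layer = "output", to = 1L, from = as.character(seq_len(ncol(x$W2))),
           weight = as.vector(x$W2)),
    tibble(layer = "output_bias", to = 1L, from = NA, weight = x$b2)
  )
}

#' @rdname tidy.mlp_model
#' @export
glance.mlp_model <- function(x, ...) {
  h <- x$history
  tibble(n_inputs = ncol(x$W1), n_hidden = nrow(x$W1), trained = x$trained,
         seed = x$seed,
         train_mse = if (is.null(h)) NA_real_ else tail(h$train_mse, 1),
         test_mse = if (is.null(h)) NA_real_ else min(h$test_mse))
}
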