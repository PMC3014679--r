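#' Takagi-Sugeno neurofuzzy model of the fuzzy-PI action
#'
#' First-order Takagi-Sugeno fuzzy system over (error, change of error) with
#' triangular premise membership functions and linear consequents
#' \eqn{\Delta U = p\,\epsilon + q\,\Delta\epsilon + r} per rule, combined by
#' normalized firing strengths (product t-norm). The error axis carries 3
#' membership functions (ZR, PS, PL -- the operating data are dominated by
#' zero-to-positive errors) or 4 (adding PM); the change-of-error axis always
#' carries the full seven-term partition, giving 21 or 28 rules.
#'
#' Premise functions are stored as vertex triples (left, apex, right); the
#' outermost function on each axis is shoulder-clamped so the universes stay
#' covered. With 3 error terms the apexes start at 0, 0.5, 1 with ZR's
#' shoulder covering the negative half of the universe.
#'
#' @param n_eps_mf 3 or 4 premise functions on the error axis.
#' @param eps_range,deps_range,du_range Universe bounds (defaults match
#'   [fuzzy_pi()]).
#' @param setpoint Set point, degC (used when wrapped as a controller).
#' @return An object of class `ts_model` (untrained: zero consequents).
#' @seealso [anfis_train()], [ts_forward()], [as_controller()]
#' @export
ts_model <- function(n_eps_mf = 3, eps_range = c(-1, 1), deps_range = c(-0.5, 0.5),
                     du_range = c(-20, 13), setpoint = 5) {
  if (!n_eps_mf %in% c(3L, 4L)) {
    abort("n_eps_mf must be 3 or 4", class = "precool_config_error")
  }
  eps_labels <- if (n_eps_mf == 3) c("ZR", "PS", "PL") else c("ZR", "PS", "PM", "PL")
  apex <- seq(0, eps_range[2], length.out = n_eps_mf)
  PE <- t(vapply(seq_len(n_eps_mf), function(i) {
    a <- apex[i]
    l <- if (i == 1) eps_range[1] else apex[i - 1]
    r <- if (i == n_eps_mf) eps_range[2] + (apex[2] - apex[1]) else apex[i + 1]
    c(l, a, r)
  }, numeric(3)))
  ap7 <- c(seq(deps_range[1], 0, length.out = 4L)[1:3], seq(0, deps_range[2], length.out = 4L))
  PD <- t(vapply(1:7, function(i) {
    a <- ap7[i]
    l <- if (i == 1) ap7[1] - (ap7[2] - ap7[1]) else ap7[i - 1]
    r <- if (i == 7) ap7[7] + (ap7[7] - ap7[6]) else ap7[i + 1]
    c(l, a, r)
  }, numeric(3)))
  dimnames(PE) <- list(eps_labels, c("left", "apex", "right"))
  dimnames(PD) <- list(fuzzy_terms(), c("left", "apex", "right"))
  structure(list(
    PE = PE, PD = PD,
    consequents = matrix(0, n_eps_mf * 7L, 3L,
                         dimnames = list(NULL, c("p", "q", "r"))),
    eps_range = eps_range, deps_range = deps_range, du_range = du_range,
    setpoint = setpoint, trained = FALSE, history = NULL
  ), class = "ts_model")
}

## premise weights for one axis: capped triangles, shoulder-clamped ends
ts_weights <- function(x, P) {
  n <- nrow(P)
  W <- vapply(seq_len(n), function(i) {
    l <- P[i, 1]; a <- P[i, 2]; r <- P[i, 3]
    up <- if (i == 1) rep(1, length(x)) else (x - l) / max(a - l, 1e-9)
    dn <- if (i == n) rep(1, length(x)) else (r - x) / max(r - a, 1e-9)
    pmax(pmin(pmin(up, dn), 1), 0)
  }, numeric(length(x)))
  if (length(x) == 1L) W <- matrix(W, nrow = 1L)
  W
}

## normalized rule firing strengths (n x n_rules), product t-norm
ts_firing <- function(model, eps, deps) {
  WE <- ts_weights(eps, model$PE)
  WD <- ts_weights(deps, model$PD)
  ne <- nrow(model$PE)
  n <- length(eps)
  Wn <- matrix(0, n, ne * 7L)
  for (i in seq_len(ne)) for (j in 1:7) {
    Wn[, (i - 1L) * 7L + j] <- WE[, i] * WD[, j]
  }
  rs <- rowSums(Wn)
  if (any(rs <= 0)) {
    abort("zero total firing strength: premise coverage is broken",
          class = "precool_internal_error")
  }
  Wn / rs
}

## design matrix for the linear consequents: [wbar*eps, wbar*deps, wbar]
ts_design <- function(model, eps, deps) {
  Wn <- ts_firing(model, eps, deps)
  nr <- ncol(Wn)
  X <- matrix(0, length(eps), nr * 3L)
  for (k in seq_len(nr)) {
    X[, (k - 1L) * 3L + 1L] <- Wn[, k] * eps
    X[, (k - 1L) * 3L + 2L] <- Wn[, k] * deps
    X[, (k - 1L) * 3L + 3L] <- Wn[, k]
  }
  X
}

#' Evaluate a Takagi-Sugeno model
#'
#' Weighted average of the rule consequents:
#' \eqn{\Delta U = \sum_k \bar w_k (p_k \epsilon + q_k \Delta\epsilon + r_k)}
#' with inputs clipped to the universes first.
#'
#' @param model A [ts_model()].
#' @param eps,deps Numeric vectors (recycled to common length).
#' @return Numeric vector of speed variations, %.
#' @export
ts_forward <- function(model, eps, deps) {
  n <- max(length(eps), length(deps))
  eps <- clip_to(rep_len(eps, n), model$eps_range[1], model$eps_range[2])
  deps <- clip_to(rep_len(deps, n), model$deps_range[1], model$deps_range[2])
  drop(ts_design(model, eps, deps) %*% as.vector(t(model$consequents)))
}

#' Training database for the neurofuzzy controller
#'
#' Samples of the tuned fuzzy-PI mapping \eqn{(\epsilon, \Delta\epsilon)
#' \mapsto \Delta U} with the odd/even split: odd-indexed samples (1-based)
#' train, even-indexed validate, and the full set tests.
#'
#' `anfis_dataset()` draws the samples from closed-loop fed-batch runs of the
#' fuzzy-PI controller itself (several batches started at different initial
#' temperatures), which concentrates the database on the controller's actual
#' operating region -- this is the database used to train the shipped
#' models. `anfis_dataset_grid()` instead enumerates a uniform grid over the
#' full input universes (row-major, error varying slowest), which is useful
#' for coverage studies.
#'
#' @param controller A [fuzzy_pi()] controller (the teacher).
#' @param params Calibrated [plant_params()] (closed-loop variant only).
#' @param T0 Initial bulk temperatures of the teaching batches, degC.
#' @param duration Batch duration, s.
#' @param grid_n Grid points per axis (>= 21; grid variant only).
#' @return A tibble of class `anfis_dataset`: `eps`, `deps`, `target`,
#'   `split` (`"train"`/`"validation"`).
#' @export
anfis_dataset <- function(controller, params, T0 = c(3.5, 5, 6.5, 8),
                          duration = 1200) {
  rows <- purrr::map(T0, function(T0i) {
    log <- run_fed_batch(controller, params, duration = duration, T0 = T0i)
    eps_raw <- log$T_bulk_C - controller$setpoint
    deps_raw <- c(eps_raw[1] - 0, diff(eps_raw))
    tibble(
      eps = clip_to(eps_raw, controller$vars$error$lo, controller$vars$error$hi),
      deps = clip_to(deps_raw, controller$vars$change_of_error$lo,
                     controller$vars$change_of_error$hi)
    )
  }) |> dplyr::bind_rows()
  rows$target <- purrr::map2_dbl(rows$eps, rows$deps,
                                 ~ evaluate_action(controller, .x, .y))
  rows$split <- ifelse(seq_len(nrow(rows)) %% 2L == 1L, "train", "validation")
  class(rows) <- c("anfis_dataset", class(rows))
  rows
}

#' @rdname anfis_dataset
#' @export
anfis_dataset_grid <- function(controller, grid_n = 21L) {
  if (grid_n < 21L) abort("grid_n must be >= 21", class = "precool_config_error")
  ve <- controller$vars$error
  vd <- controller$vars$change_of_error
  rows <- tidyr::expand_grid(
    eps = seq(ve$lo, ve$hi, length.out = as.integer(grid_n)),
    deps = seq(vd$lo, vd$hi, length.out = as.integer(grid_n))
  )
  rows$target <- purrr::map2_dbl(rows$eps, rows$deps,
                                 ~ evaluate_action(controller, .x, .y))
  rows$split <- ifelse(seq_len(nrow(rows)) %% 2L == 1L, "train", "validation")
  class(rows) <- c("anfis_dataset", class(rows))
  rows
}

## least-squares consequent solve at fixed premises; rules that the data
## barely fire leave the system singular, in which case a ridge penalty
## (scaled to the design) keeps their coefficients bounded
ts_solve_consequents <- function(model, data_train, quiet = FALSE) {
  X <- ts_design(model, data_train$eps, data_train$deps)
  y <- data_train$target
  qrX <- qr(X)
  if (qrX$rank < ncol(X)) {
    if (!quiet) warn("singular consequent system; using scaled ridge fallback")
    G <- crossprod(X)
    lambda <- 1e-6 * mean(diag(G))
    beta <- solve(G + diag(lambda, ncol(X)), crossprod(X, y))
  } else {
    beta <- qr.coef(qrX, y)
  }
  beta[is.na(beta)] <- 0
  matrix(beta, ncol = 3L, byrow = TRUE, dimnames = list(NULL, c("p", "q", "r")))
}

#' Root-mean-square mimicry error of a Takagi-Sugeno model
#'
#' RMSE of the model against the target actions of a dataset, in \eqn{\Delta
#' U} units (%). The headline adequacy figure: coincidence with the teacher
#' corresponds to an RMSE of a fraction of a percent of the 33-unit output
#' span.
#'
#' @param model A [ts_model()].
#' @param data An [anfis_dataset()] (any subset).
#' @return RMSE, % pump speed.
#' @export
ts_rmse <- function(model, data) {
  sqrt(mean((ts_forward(model, data$eps, data$deps) - data$target)^2))
}

## pack/unpack trainable premise parameters (unused shoulder feet masked out)
ts_premise_pack <- function(model) {
  ne <- nrow(model$PE)
  pe_mask <- matrix(TRUE, ne, 3); pe_mask[1, 1] <- FALSE; pe_mask[ne, 3] <- FALSE
  pd_mask <- matrix(TRUE, 7, 3); pd_mask[1, 1] <- FALSE; pd_mask[7, 3] <- FALSE
  list(par = c(t(model$PE))[c(t(pe_mask))], pd = c(t(model$PD))[c(t(pd_mask))],
       pe_mask = pe_mask, pd_mask = pd_mask)
}

ts_premise_apply <- function(model, pe_par, pd_par, masks) {
  PE <- t(model$PE); PE[t(masks$pe_mask)] <- pe_par; model$PE <- t(PE)
  PD <- t(model$PD); PD[t(masks$pd_mask)] <- pd_par; model$PD <- t(PD)
  ## keep every triple ordered with a minimal width
  fix <- function(P, span) {
    eps <- 1e-3 * span
    P[, 1] <- pmin(P[, 1], P[, 2] - eps)
    P[, 3] <- pmax(P[, 3], P[, 2] + eps)
    P
  }
  model$PE <- fix(model$PE, diff(model$eps_range))
  model$PD <- fix(model$PD, diff(model$deps_range))
  model
}

#' Train a Takagi-Sugeno model by hybrid learning
#'
#' Classic two-pass hybrid estimation: in every epoch the linear consequents
#' are solved globally by least squares at fixed premises, then the premise
#' vertex parameters take one gradient-descent step on the training MSE
#' (central finite differences, step scaled to the universe span). The
#' validation RMSE is monitored: when it worsens the premise step is undone
#' and the learning rate halved, and the epoch-best model (by validation
#' RMSE) is returned. `epochs = 0` leaves the premises untouched and performs
#' the single consequent solve.
#'
#' @param model A [ts_model()].
#' @param data An [anfis_dataset()].
#' @param epochs Training epochs (default 100).
#' @param lr Initial premise learning rate as a fraction of the universe span
#'   moved per epoch (default 0.01).
#' @return The trained model; `$history` holds per-epoch train/validation
#'   RMSE.
#' @export
anfis_train <- function(model, data, epochs = 100L, lr = 0.01) {
  if (nrow(data) == 0) abort("empty training data", class = "precool_config_error")
  tr <- dplyr::filter(data, .data$split == "train")
  va <- dplyr::filter(data, .data$split == "validation")
  if (nrow(va) == 0) va <- tr
  model$consequents <- ts_solve_consequents(model, tr)
  best <- model
  best_val <- ts_rmse(model, va)
  hist <- list(tibble(epoch = 0L, train_rmse = ts_rmse(model, tr),
                      val_rmse = best_val, lr = lr))
  masks <- ts_premise_pack(model)
  if (epochs > 0) {
    for (ep in seq_len(epochs)) {
      packed <- ts_premise_pack(model)
      par <- c(packed$par, packed$pd)
      n_pe <- length(packed$par)
      span <- c(rep(diff(model$eps_range), n_pe),
                rep(diff(model$deps_range), length(packed$pd)))
      mse_of <- function(p) {
        m <- ts_premise_apply(model, p[seq_len(n_pe)], p[-seq_len(n_pe)], masks)
        mean((ts_forward(m, tr$eps, tr$deps) - tr$target)^2)
      }
      h <- 1e-4 * span
      g <- vapply(seq_along(par), function(i) {
        pp <- par; pp[i] <- pp[i] + h[i]; fp <- mse_of(pp)
        pp[i] <- par[i] - h[i]; fm <- mse_of(pp)
        (fp - fm) / (2 * h[i])
      }, numeric(1))
      gs <- g * span
      denom <- max(abs(gs))
      if (denom > 0) {
        step <- -lr * span * gs / denom
        cand <- ts_premise_apply(model, (par + step)[seq_len(n_pe)],
                                 (par + step)[-seq_len(n_pe)], masks)
        cand$consequents <- ts_solve_consequents(cand, tr, quiet = TRUE)
        val <- ts_rmse(cand, va)
        if (val <= ts_rmse(model, va)) {
          model <- cand
        } else {
          lr <- lr / 2           # premise step rejected
        }
        if (val < best_val) { best_val <- val; best <- model }
      }
      hist[[ep + 1L]] <- tibble(epoch = ep, train_rmse = ts_rmse(model, tr),
                                val_rmse = ts_rmse(model, va), lr = lr)
    }
  }
  best$trained <- TRUE
  best$history <- dplyr::bind_rows(hist)
  best
}

#' Wrap a trained model as an incremental controller
#'
#' Gives the Takagi-Sugeno model (or, in principle, any static
#' \eqn{(\epsilon, \Delta\epsilon) \to \Delta U} map) the same incremental
#' interface as [fuzzy_pi()]: error computation, clipping, output clamped to
#' the speed-variation universe, and integration onto the previous pump
#' speed.
#'
#' @param model A trained [ts_model()].
#' @param U0 Initial pump speed, %.
#' @return An object of class `c("ts_controller", "controller")`.
#' @export
as_controller <- function(model, U0 = 40) {
  UseMethod("as_controller")
}

#' @rdname as_controller
#' @export
as_controller.ts_model <- function(model, U0 = 40) {
  structure(list(
    model = model, setpoint = model$setpoint,
    vars = list(
      error = list(lo = model$eps_range[1], hi = model$eps_range[2]),
      change_of_error = list(lo = model$deps_range[1], hi = model$deps_range[2])
    ),
    state = list(prev_error = 0, prev_speed = U0)
  ), class = c("ts_controller", "controller"))
}

#' @rdname control_step
#' @export
control_step.ts_controller <- function(controller, measured_T, obs = NULL) {
  eps_raw <- measured_T - controller$setpoint
  deps_raw <- eps_raw - controller$state$prev_error
  m <- controller$model
  dU <- clip_to(ts_forward(m, eps_raw, deps_raw), m$du_range[1], m$du_range[2])
  U_new <- clip_to(controller$state$prev_speed + dU, 0, 100)
  controller$state$prev_error <- eps_raw
  controller$state$prev_speed <- U_new
  list(controller = controller, U = U_new, dU = dU)
}

#' @export
evaluate_action.ts_controller <- function(controller, eps, deps) {
  m <- controller$model
  clip_to(ts_forward(m, eps, deps), m$du_range[1], m$du_range[2])
}

#' Tidy / glance methods for Takagi-Sugeno models
#'
#' @param x A [ts_model()].
#' @param ... Unused.
#' @return `tidy()`: one row per rule with premise terms and consequent
#'   coefficients; `glance()`: one row with rule count and final RMSEs.
#' @export
tidy.ts_model <- function(x, ...) {
  ne <- nrow(x$PE)
  tidyr::expand_grid(error = rownames(x$PE), change_of_error = rownames(x$PD)) |>
    mutate(p = x$consequents[, "p"], q = x$consequents[, "q"],
           r = x$consequents[, "r"])
}

#' @rdname tidy.ts_model
#' @export
glance.ts_model <- function(x, ...) {
  h <- x$history
  tibble(
    n_rules = nrow(x$consequents),
    n_eps_mf = nrow(x$PE),
    trained = x$trained,
    epochs = if (is.null(h)) 0L else max(h$epoch),
    train_rmse = if (is.null(h)) NA_real_ else tail(h$train_rmse, 1),
    val_rmse = if (is.null(h)) NA_real_ else min(h$val_rmse)
  )
}

#' Serialize a Takagi-Sugeno model to/from JSON
#'
#' @param model A [ts_model()].
#' @param path File path.
#' @return `ts_write_json()` returns `path` invisibly; `ts_read_json()` the
#'   model.
#' @export
ts_write_json <- function(model, path) {
  obj <- list(
    n_eps_mf = nrow(model$PE),
    eps_labels = rownames(model$PE),
    PE = unname(model$PE), PD = unname(model$PD),
    consequents = unname(model$consequents),
    eps_range = model$eps_range, deps_range = model$deps_range,
    du_range = model$du_range, setpoint = model$setpoint,
    trained = model$trained
  )
  jsonlite::write_json(obj, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname ts_write_json
#' @export
ts_read_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  model <- ts_model(n_eps_mf = obj$n_eps_mf, eps_range = obj$eps_range,
                    deps_range = obj$deps_range, du_range = obj$du_range,
                    setpoint = obj$setpoint)
  model$PE[] <- obj$PE
  model$PD[] <- obj$PD
  model$consequents[] <- obj$consequents
  model$trained <- isTRUE(obj$trained)
  model
}
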