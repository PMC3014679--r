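## Independent reference implementations used to cross-check the package.
## Deliberately written as plain nested loops over explicit vertex geometry,
## sharing no code with the package internals.

## triangular membership from explicit vertices; shoulder via +-Inf feet
oracle_tri <- function(x, left, apex, right) {
  if (x < left || x > right) return(0)
  if (x == apex) return(1)
  if (x < apex) {
    if (is.infinite(left)) 1 else (x - left) / (apex - left)
  } else {
    if (is.infinite(right)) 1 else (right - x) / (right - apex)
  }
}

## vertex table of the package's 7-term layout on [lo, hi] (ZR apex at 0,
## evenly spaced per side, shoulder-clamped ends)
oracle_layout <- function(lo, hi) {
  apex <- c(lo, lo * 2 / 3, lo / 3, 0, hi / 3, hi * 2 / 3, hi)
  data.frame(
    term = c("NL", "NM", "NS", "ZR", "PS", "PM", "PL"),
    left = c(-Inf, apex[1:6]),
    apex = apex,
    right = c(apex[2:7], Inf)
  )
}

## output-term membership sampled on the centroid grid, from the oracle's
## own vertex table (built once per layout and reused across calls)
oracle_out_mat <- function(du_rng, n_grid) {
  lu <- oracle_layout(du_rng[1], du_rng[2])
  u <- seq(du_rng[1], du_rng[2], length.out = n_grid)
  mat <- matrix(0, 7, n_grid)
  for (k in 1:7) {
    for (g in seq_len(n_grid)) {
      mat[k, g] <- oracle_tri(u[g], lu$left[k], lu$apex[k], lu$right[k])
    }
  }
  list(u = u, mat = mat, term = lu$term)
}

## full brute-force Mamdani pipeline: enumerate all 49 rules, clip each
## consequent area, aggregate by pointwise max, discrete centroid
oracle_mamdani <- function(eps, deps, table, n_grid = 10001,
                           eps_rng = c(-1, 1), deps_rng = c(-0.5, 0.5),
                           du_rng = c(-20, 13), out = NULL) {
  le <- oracle_layout(eps_rng[1], eps_rng[2])
  ld <- oracle_layout(deps_rng[1], deps_rng[2])
  if (is.null(out)) out <- oracle_out_mat(du_rng, n_grid)
  eps <- min(max(eps, eps_rng[1]), eps_rng[2])
  deps <- min(max(deps, deps_rng[1]), deps_rng[2])
  agg <- rep(0, length(out$u))
  for (i in 1:7) {
    mu_e <- oracle_tri(eps, le$left[i], le$apex[i], le$right[i])
    if (mu_e == 0) next
    for (j in 1:7) {
      mu_d <- oracle_tri(deps, ld$left[j], ld$apex[j], ld$right[j])
      if (mu_d == 0) next
      w <- min(mu_e, mu_d)
      k <- match(table[i, j], out$term)
      agg <- pmax(agg, pmin(out$mat[k, ], w))
    }
  }
  sum(out$u * agg) / sum(agg)
}

## independent Takagi-Sugeno forward pass: explicit loops, no matrices
oracle_ts_forward <- function(model, eps, deps) {
  eps <- min(max(eps, model$eps_range[1]), model$eps_range[2])
  deps <- min(max(deps, model$deps_range[1]), model$deps_range[2])
  ne <- nrow(model$PE)
  tri <- function(x, l, a, r, shoulder_l, shoulder_r) {
    up <- if (shoulder_l) 1 else (x - l) / (a - l)
    dn <- if (shoulder_r) 1 else (r - x) / (r - a)
    max(min(up, dn, 1), 0)
  }
  num <- 0; den <- 0
  for (i in seq_len(ne)) {
    we <- tri(eps, model$PE[i, 1], model$PE[i, 2], model$PE[i, 3],
              i == 1, i == ne)
    for (j in 1:7) {
      wd <- tri(deps, model$PD[j, 1], model$PD[j, 2], model$PD[j, 3],
                j == 1, j == 7)
      w <- we * wd
      k <- (i - 1) * 7 + j
      out <- model$consequents[k, "p"] * eps + model$consequents[k, "q"] * deps +
        model$consequents[k, "r"]
      num <- num + w * unname(out)
      den <- den + w
    }
  }
  num / den
}

## independent feedforward pass: scalar loops over the weight entries
oracle_mlp_forward <- function(model, x) {
  s <- model$scaling
  xs <- numeric(length(x))
  for (j in seq_along(x)) {
    rng <- s$x_max[j] - s$x_min[j]
    xs[j] <- if (rng > 0) 2 * (x[j] - s$x_min[j]) / rng - 1 else 0
  }
  h <- numeric(nrow(model$W1))
  for (i in seq_len(nrow(model$W1))) {
    acc <- model$b1[i]
    for (j in seq_along(xs)) acc <- acc + model$W1[i, j] * xs[j]
    h[i] <- tanh(acc)
  }
  ys <- model$b2
  for (i in seq_along(h)) ys <- ys + model$W2[1, i] * h[i]
  if (s$y_max > s$y_min) (ys + 1) / 2 * (s$y_max - s$y_min) + s$y_min else s$y_min
}

## trapezoidal integral oracle on an arbitrary sampled signal
oracle_trapz <- function(t, f) {
  sum((f[-1] + f[-length(f)]) / 2 * diff(t))
}
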