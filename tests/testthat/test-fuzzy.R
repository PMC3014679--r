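test_that("controller inputs follow the error definitions and clip to the universes", {
  ctrl <- fuzzy_pi("tuned", setpoint = 5)

  inp <- compute_inputs(ctrl, 5.0)                  # at set point, no history
  expect_equal(c(inp$eps, inp$deps), c(0, 0))

  ctrl$state$prev_error <- 2.0                      # warm and rising
  inp <- compute_inputs(ctrl, 8.1)
  expect_equal(c(inp$eps_raw, inp$deps_raw), c(3.1, 1.1))
  expect_equal(inp$eps, 1.0)                        # clipped to [-1, 1]
  expect_equal(inp$deps, 0.5)                       # clipped to [-0.5, 0.5]

  ctrl$state$prev_error <- -0.5
  inp <- compute_inputs(ctrl, 4.0)
  expect_equal(c(inp$eps, inp$deps), c(-1.0, -0.5))
})

test_that("min inference fires the expected rules", {
  ctrl <- fuzzy_pi("tuned")

  fired <- fuzzy_infer(ctrl, 0, 0)                  # both at the ZR apex
  expect_equal(fired$term, "ZR")
  expect_equal(fired$strength, 1)

  ## eps at the PS apex, deps midway between the ZR and PS apexes: only the
  ## PS row fires, split between the ZR and PS columns at strength 0.5
  ve <- ctrl$vars$error; vd <- ctrl$vars$change_of_error
  fired <- fuzzy_infer(ctrl, ve$mfs$PS$apex,
                       (vd$mfs$ZR$apex + vd$mfs$PS$apex) / 2)
  tab <- rule_table("tuned")
  expect_setequal(fired$term, unique(c(tab["PS", "ZR"], tab["PS", "PS"])))
  expect_equal(fired$strength, rep(0.5, nrow(fired)))

  fired <- fuzzy_infer(ctrl, ve$lo, vd$lo)          # saturated corner
  expect_equal(fired$term, "NL")
  expect_equal(fired$strength, 1)
})

test_that("centroid defuzzification matches symmetry, bounds and a fine-grid oracle", {
  ## symmetric output universe: a clipped ZR area has centroid exactly 0
  sym <- fuzzy_pi("tuned", du_range = c(-20, 20), n_grid = 10001)
  for (s in c(0.2, 0.5, 1)) {
    expect_equal(defuzzify(sym, tibble::tibble(term = "ZR", strength = s)), 0,
                 tolerance = 1e-12)
  }

  ## a PL shoulder area lands between the PM apex and the upper bound
  ctrl <- fuzzy_pi("tuned")
  val <- defuzzify(ctrl, tibble::tibble(term = "PL", strength = 0.7))
  expect_gt(val, ctrl$vars$speed_variation$mfs$PM$apex)
  expect_lte(val, ctrl$vars$speed_variation$hi)

  ## two clipped areas against an independent high-resolution centroid
  fine <- fuzzy_pi("tuned", n_grid = 100001L)
  got <- defuzzify(fine, tibble::tibble(term = c("PS", "PM"), strength = 0.5))
  lay <- oracle_layout(-20, 13)
  u <- seq(-20, 13, length.out = 100001L)
  agg <- rep(0, length(u))
  for (k in c(5, 6)) {   # PS, PM
    mk <- vapply(u, oracle_tri, numeric(1), lay$left[k], lay$apex[k], lay$right[k])
    agg <- pmax(agg, pmin(mk, 0.5))
  }
  expect_equal(got, sum(u * agg) / sum(agg), tolerance = 1e-12)

  expect_error(defuzzify(ctrl, tibble::tibble(term = "ZR", strength = 0)),
               class = "precool_internal_error")
  expect_error(fuzzy_pi(n_grid = 51), class = "precool_config_error")
})

test_that("one controller step integrates and clamps the pump speed", {
  ## symmetric output universe: exactly zero action at steady state
  ctrl <- fuzzy_pi("tuned", du_range = c(-20, 20), U0 = 40)
  st <- control_step(ctrl, 5.0)
  expect_equal(st$dU, 0, tolerance = 1e-12)
  expect_equal(st$U, 40)

  ## large positive action from high prev_speed saturates at 100
  ctrl <- fuzzy_pi("tuned", U0 = 98)
  ctrl$state$prev_error <- 0.5
  st <- control_step(ctrl, 6.0)                      # eps = 1, deps = 0.5 -> PL
  expect_gt(st$dU, 8)
  expect_equal(st$U, 100)
  expect_equal(st$controller$state$prev_speed, 100)
  expect_equal(st$controller$state$prev_error, 1.0)
})

test_that("the pipeline equals the brute-force Mamdani oracle on a 21x21 grid", {
  for (nm in c("original", "tuned")) {
    ctrl <- fuzzy_pi(nm, n_grid = 10001L)
    tab <- rule_table(nm)
    out <- oracle_out_mat(c(-20, 13), 10001L)
    eg <- seq(-1, 1, length.out = 21)
    dg <- seq(-0.5, 0.5, length.out = 21)
    worst <- 0
    for (e in eg) for (d in dg) {
      got <- evaluate_action(ctrl, e, d)
      want <- oracle_mamdani(e, d, tab, out = out)
      worst <- max(worst, abs(got - want) / max(abs(want), 1e-12))
    }
    expect_lt(worst, 1e-9)
  }
})

test_that("the action stays inside the speed-variation universe everywhere", {
  ctrl <- fuzzy_pi("tuned")
  set.seed(42)
  eps <- runif(300, -3, 3)          # includes out-of-universe inputs
  deps <- runif(300, -2, 2)
  du <- mapply(function(e, d) evaluate_action(ctrl, e, d), eps, deps)
  expect_true(all(du >= -20 - 1e-9))
  expect_true(all(du <= 13 + 1e-9))
})

test_that("a symmetric reference configuration gives an antisymmetric, rising surface", {
  ctrl <- fuzzy_pi("original", du_range = c(-20, 20), n_grid = 10001L)
  eg <- seq(-1, 1, length.out = 17)
  dg <- seq(-0.5, 0.5, length.out = 17)
  span <- 40
  S <- outer(eg, dg, Vectorize(function(e, d) evaluate_action(ctrl, e, d)))
  ## antisymmetry: S(eps, deps) = -S(-eps, -deps)
  expect_lt(max(abs(S + S[rev(seq_along(eg)), rev(seq_along(dg))])) / span, 1e-6)
  ## the action rises with the error at every fixed change-of-error; the
  ## discrete centroid is allowed its small well-known local dips (they stay
  ## under 2 % of the output span), but every column must climb end to end
  ## and the dips must never dominate
  dips <- apply(S, 2, function(col) min(diff(col)))
  expect_true(all(dips > -0.02 * span))
  ## corner columns are compressed by saturation but still climb ~18 units
  expect_true(all(S[17, ] - S[1, ] > 0.4 * span))
})

test_that("control surface export has the documented shape and signs", {
  ctrl <- fuzzy_pi("tuned")
  surf <- control_surface(ctrl, resolution = 21)
  expect_named(surf, c("epsilon", "delta_epsilon", "delta_u"))
  expect_equal(nrow(surf), 441)
  ## epsilon varies slowest (row-major)
  expect_equal(surf$epsilon[1:21], rep(-1, 21))

  ## warm bulk already cooling fast: softened NS consequent, negative action
  corner <- surf$delta_u[surf$epsilon == 1 & surf$delta_epsilon == -0.5]
  expect_lt(corner, 0)

  ## symmetric configuration passes through zero at the origin
  sym <- control_surface(fuzzy_pi("original", du_range = c(-20, 20)),
                         resolution = 21)
  expect_equal(sym$delta_u[sym$epsilon == 0 & sym$delta_epsilon == 0], 0,
               tolerance = 1e-12)

  expect_error(control_surface(ctrl, resolution = 5), class = "precool_config_error")

  ## CSV round trip with the fixed header
  path <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(surf, path)
  expect_identical(readLines(path, n = 1), "epsilon,delta_epsilon,delta_u")
})
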