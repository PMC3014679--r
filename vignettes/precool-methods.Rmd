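---
title: "Models and methods behind precool"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind precool}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

precool is a simulation workbench for the temperature-control problem that
arises when a heat-sensitive proteolytic enzyme (bromelain, EC 3.4.22.4) is
recovered from pineapple extract by cold-ethanol precipitation in a fed-batch
jacketed tank. The bulk must be held near 5 °C to avoid denaturation, but the
process fights back: ethanol enters at room temperature, its dissolution is
exothermic and strongest at the start of the batch, and the heat-transfer
area grows as the tank fills. The package provides a calibrated digital twin
of the tank and three controllers that act on the coolant pump speed — an
incremental Mamdani fuzzy-PI controller, a Takagi–Sugeno neurofuzzy mimic of
it, and a neural one-step-ahead model predictive controller — together with
the performance indices used to compare them. This vignette records the
models, the parameter choices, and the design decisions that were genuinely
open.

## The plant model

The tank is modelled as a single well-mixed compartment:

$$\rho c_p V \frac{dT}{dt} = \underbrace{A_f\,(T_{eth} - T)}_{\text{feed
sensible heat}} + \underbrace{Q_d(V)}_{\text{dissolution heat}}
- \underbrace{K(V)\,(U/100)^{\gamma(V)}\,(T - T_{c,in})}_{\text{jacket duty}}
\qquad \frac{dV}{dt} = F_{eth}\ \text{until } V_{max}$$

with $F_{eth} = 0.6$ mL/s (2.16 L/h), $V$ from 150 to 750 mL (so the fill
takes 1000 s ≈ 17 min), $T_{eth} = 23$ °C, coolant inlet at 0 °C, and
$\rho c_p = 3.2$ J/(mL·°C) for the water–ethanol bulk. $A_f = c_{p,eth}
F_{eth} = 1.44$ W/°C is the heat-capacity flow of the feed.

Three quantities carry the volume dependence and are *identified from data*
rather than assumed: the jacket duty scale $K(V)$, the pump-law exponent
$\gamma(V)$, and the dissolution heat $Q_d(V)$. Each is a quadratic in $V$
through values solved exactly at the three reaction-curve volumes (below).
In pseudosteady (reaction-curve) mode the volume is held constant by
exchanging prediluted extract at equal rates; that stream enters cold
(default 0 °C) with a heat-capacity flow $W$ = 5.56 W/°C (≈ 5.6 L/h of
mixture) and is absent in fed-batch mode.

### Calibration

The published characterisation of this process consists of six static gains
$K_p = \Delta T_{ss}/|\Delta U|$ from ±30 % pump steps at 300, 450 and
600 mL, all started at 40 % pump speed and 5 °C:

| V (mL) | dilution | $K_p^{+30}$ | $K_p^{-30}$ |
|---|---|---|---|
| 300 | 1:1 | −0.030 | +0.030 |
| 450 | 1:2 | −0.047 | +0.020 |
| 600 | 1:3 | −0.053 | +0.010 |

(The table convention signs the gain by the direction of the temperature
response, hence positive entries for negative steps.)

The gain pattern is strongly asymmetric: up-steps bite harder as the tank
fills while down-steps fade. Within a one-compartment balance with a shared
power-law pump characteristic this pattern pins the model down almost
completely — a useful fact we exploit instead of fighting. At each test
volume, three conditions (curve starts at 5 °C at 40 %, and the two printed
gains) determine three local parameters $(K_V, \gamma_V, Q_{d,V})$ exactly:
$\gamma_V$ solves a one-dimensional root problem (`stats::uniroot` on a
bracketed sign change, keeping the branch with positive cooling), and the
other two follow in closed form. A least-squares calibration over a smaller
shared parameter set was tried first and cannot come close to the printed
precision (its best residual is ~30× the 0.0005 °C/% tolerance), which is
why the identification is exact-by-construction instead. The solved values
are physically coherent without being constrained to be: $K$ grows with
volume (the wetted jacket area grows), $Q_d$ decays with dilution (9.4 →
4.0 W), and $\gamma$ grows (pump speed matters more when the exchange area
is no longer limiting).

```{r calibration, eval = FALSE}
library(precool)
plant <- default_plant()       # calibrate_plant(plant_params())
tidy(plant$calibration)
#>    V_mL dilution     K gamma    Qd
#> 1   300 1:1       5.63  1.45  9.37
#> 2   450 1:2      10.4   2.72  6.19
#> 3   600 1:3      16.0   3.97  3.99
measure_static_gains(plant)    # re-measures all six via the ODE protocol
```

`measure_static_gains()` does not reuse the closed forms: it integrates the
reaction curves with the plant's RK4 integrator until a steady-state
criterion is met and estimates the gains from the simulated traces, exactly
as the protocol prescribes. All six printed values are recovered to three
decimals.

The quadratic interpolants are evaluated across the full 150–750 mL
fed-batch range, with floors ($K \ge 0.3$ W/°C, $\gamma \ge 0.05$, $Q_d \ge
0$) guarding extrapolation. At 150 mL they give a weak, nearly
speed-insensitive jacket and a ~13.5 W dissolution load — which is exactly
why every controller overshoots early in the batch: below roughly 340 mL
even a flat-out pump cannot absorb the feed plus dissolution heat at 5 °C.
The early excursion in the simulator is therefore structural, as it was in
the pilot plant.

### Integration and determinism

Fixed-step RK4 with `ode_dt = 0.25` s, controller consulted every 4 s (the
sample time used throughout). Halving the step changes logged temperatures
by far less than 1e−4 °C (tested). Measurement noise is off by default so
every run is reproducible; a Gaussian sensor noise of configurable standard
deviation can be enabled and is driven by the experiment seed.

## The fuzzy-PI controller

The controller is incremental (velocity form): inputs are the error
$\epsilon = T - T_{sp}$ and its change $\Delta\epsilon$, the output is a
pump-speed change $\Delta U$ integrated onto the previous speed and clamped
to [0, 100] %. Universes: $\epsilon \in [-1, 1]$ °C (deliberately narrow —
small deviations already provoke strong action), $\Delta\epsilon \in
[-0.5, 0.5]$ °C/sample, $\Delta U \in [-20, 13]$ %. The asymmetric output
universe lets the controller back off quickly once the dissolution excursion
turns over. $\Delta\epsilon$'s universe is not a published value; ±0.5 °C
per 4 s sample matches the fastest slews the calibrated plant produces and
is configurable.

Seven triangular membership functions cover each universe with the standard
50 %-overlap layout and shoulder-clamped end terms. On an asymmetric
universe the apexes are spaced evenly *per side of zero* so that the ZR term
peaks at 0; spacing them evenly across [−20, 13] would put ZR's apex at
−3.5 %, a standing negative bias that makes the closed loop drift and hunt
(we verified this variant; it cannot hold the set point). On symmetric
universes the two layouts coincide. Even so, the ZR *area* on [−20, 13] is
asymmetric (support −6.7 to +4.3), so the centroid at perfect steady state
is −0.78 % rather than 0; in closed loop this only shifts the equilibrium
error by ≈ +0.05 °C and is the honest behaviour of a centroid defuzzifier
on this universe.

Inference is classical Mamdani max–min: firing strength = min of the two
antecedent memberships, same-consequent rules aggregated by max, output
areas clipped and combined by pointwise max, crisp action = discrete
centroid on a 10001-point grid (results change by <1e−6 of span beyond
~1000 points; the grid is configurable and all area combination is exact on
it). Inputs are clipped to their universes before fuzzification, which
together with the shoulder terms guarantees a nonempty fired set.

Two properties of this construction are worth stating because they are
often assumed away. First, the centroid surface is *not* pointwise monotone:
when a new output area enters the aggregation the centroid can retreat by up
to ~1.5 % of the span even under the canonical rule table (our tests bound
these dips rather than pretending they vanish). Second, the tuned rule
table is intentionally non-monotone: its six softened cells (the PL row
under falling error, and the PL column at small errors) trade aggression
for damping exactly where the early-batch physics would otherwise cause
saturation and oscillation.

## The Takagi–Sugeno neurofuzzy controller

The neurofuzzy controller reproduces the tuned fuzzy-PI mapping as a
first-order Takagi–Sugeno system: 3 (or 4) triangular premise terms on
$\epsilon$ × 7 on $\Delta\epsilon$, product t-norm, normalized firing
strengths weighting per-rule linear consequents $p\epsilon + q\Delta\epsilon
+ r$ (21 or 28 rules).

**Training database.** The database is generated by *operating* the tuned
fuzzy-PI controller: four closed-loop batches started at 3.5, 5, 6.5 and
8 °C, sampled every 4 s (1200 samples), with the teacher's own action as
target. Odd-indexed samples train, even-indexed validate, and the full set
is the test set. We deliberately do not train on a uniform grid over the
input universes: a triangular-premise TS system with only 3–4 error terms
cannot represent the full Mamdani surface to the fidelity we demand (the
best achievable full-grid RMSE is ≈ 1.4 % of the output span even when
every premise vertex is optimized), whereas on the operating distribution —
which is what the controller will actually see in closed loop — the mimicry
is nearly exact. The operating data also explain the seemingly odd premise
vocabulary: ~97 % of closed-loop error samples are non-negative (the batch
overshoots, returns, and then regulates), so the error axis carries ZR, PS,
PL (and PM in the 4-term variant) with ZR's shoulder covering the rarely
visited negative half. A uniform-grid generator is retained
(`anfis_dataset_grid()`) for coverage studies.

**Hybrid learning.** Each of the 100 epochs solves the linear consequents
globally by least squares at fixed premises, then takes one gradient step on
the premise vertices (central differences, step bounded to 1 % of the
universe span, halved whenever the validation RMSE worsens); the
epoch-best model by validation RMSE is returned. Closed-loop data fire only
a subset of the rules, so the consequent system is rank-deficient; a ridge
penalty scaled to the design (λ = 1e−6 × mean diagonal of the normal
matrix) keeps the unexercised rules' coefficients bounded instead of letting
the solver assign them arbitrary values — without it the validation error
triples. Trained this way, the 3-term variant reaches RMSE ≈ 0.21 % pump
speed and the 4-term variant ≈ 0.15, both well under 1 % of the 33-unit
output span — the mimic and teacher are coincident for practical purposes.

**A consequence worth being explicit about.** Because both mimics reproduce
the teacher to a fraction of a percent, their closed-loop trajectories are
nearly indistinguishable from the teacher's and from each other: overshoots
agree to ~0.0002 °C and pump-saturation intervals to within one 4-s sample.
At this fidelity, rankings *among* the fuzzy-family controllers on a single
deterministic batch are decided by sub-resolution jitter (which side of zero
the mimic's action falls on at one near-zero crossing), not by controller
quality. The pilot-scale study could separate these controllers because its
mimics were evidently less faithful; a simulation that meets the coincidence
requirement necessarily gives up the separation. The package reports the raw
metrics and leaves the interpretation of sub-resolution differences to the
reader.

## The neural model predictive controller

A 7-input feedforward network predicts the bulk temperature one sample
ahead. Inputs at sample $k$: ethanol temperature, coolant inlet and outlet
temperatures, pump speed, liquid volume (a clock surrogate that
disambiguates otherwise identical states), pump-speed change, and current
bulk temperature. The hidden layer has 14 tanh nodes (twice the input
count); the output is linear, the regression norm. Inputs and target are
min-max scaled to [−1, 1]; features that are constant in simulation
(ethanol and coolant-inlet temperatures) scale to 0 but stay in the
architecture for fidelity to the 7-input design.

Training data are simulated: six open-loop fed-batch runs driven by seeded
random pump staircases guaranteed to touch 0 and 100 % (training role), plus
two closed-loop batches under the tuned fuzzy-PI controller (test role) —
the model must be adequate in closed-loop conditions because that is where
the optimizer will interrogate it. The split is contiguous by run; rows are
never shuffled across the train/test boundary. Weights are fit by
Levenberg–Marquardt (`minpack.lm::nls.lm`, analytic Jacobian) in rounds of
10 iterations with the held-out MSE monitored between rounds; training stops
after three rounds without improvement and keeps the best round. A fit that
cannot beat predicting the mean is retried with a fresh seed (at most 5).
Adequacy is judged the standard way, by the dispersion plot on held-out
closed-loop data: the shipped model's prediction-vs-target regression has
slope 1.000 and intercept ≈ 3e−5 °C.

At each sample the controller minimizes $(\hat T_{k+1}(U) - 5)^2$ over the
feasible interval $[\max(0, U_{k-1}-35), \min(100, U_{k-1}+35)]$ — the 35 %
rate limit smooths the solver's action — with a hard override: pump off
whenever the bulk is at or below 4.9 °C, which keeps the controlled variable
inside the model's training range. The one-dimensional solve is a 41-point
scan refined by `stats::optimize` in the bracketing cell, with near-ties
broken toward the smaller move; tests verify agreement with an exhaustive
0.01 %-resolution grid search to within 0.05 % on random instances. A
spreadsheet-style quasi-Newton solver would also work; for a box-constrained
scalar problem the bracketed scan-and-refine is simpler and its optimality
is directly checkable.

## Performance indices

All indices are computed from the logged trace and defined so smaller is
better. Overshoot is the clamped upward excursion (the excursion in this
process is always upward). ITAE is the trapezoidal $\int t\,|T-T_{sp}|dt$
from batch start. The published study reports rise and response times
without defining them, and its fuzzy-PI pair (170 s vs 171 s) shows the two
events nearly coincide; we define rise time as the first return-crossing of
the set point after an excursion beyond the settling band, and response time
as the last exit from the ±0.2 °C band (both configurable). With these
definitions the two can differ by a few samples in either order, so neither
is constrained by the other. Pump saturation time counts samples at either
rail (0 or 100 %), optionally excluding cutoff-commanded pump-off for the
predictive controller. Electric energy uses the cubic pump-affinity proxy
$\int P_{max}(U/100)^3 dt$; it ranks controllers by actuation effort and is
not comparable to metered plant figures.

On the calibrated plant, one 1200-s batch per controller under identical
conditions gives ITAE ≈ 2.2×10⁵ °C·s² for the fuzzy-PI and both mimics,
1.9×10⁵ for the MPC, and 6.9×10⁶ for the open-loop 40 % baseline — the
closed-versus-open-loop gap mirrors the published ordering (their 56.6×10³
vs 950.5×10³), while the absolute values are plant-specific and not
comparable.

## What the simulator does and does not show

The twin reproduces: the fill arithmetic (150→750 mL at 2.16 L/h ≈ 17 min),
all six static gains to printed precision, the early dissolution-heat
overshoot with its physical inevitability, the asymmetric gain pattern, and
the qualitative closed-loop story (every tuned controller beats open loop by
>an order of magnitude in ITAE; the MPC saturates longest because its rate
limit makes it ride the rails).

It does not attempt: spatial gradients or mixing effects, precipitation
kinetics or enzyme-activity prediction, actuator and sensor dynamics,
Fieldbus latencies, or the pilot plant's closed-loop dynamic constants —
the published reaction curves fix only static gains, so rise times, ITAEs
and saturation intervals are this plant's own, and only their orderings are
meaningful against the published table. Passing tests therefore certify the
algorithms and the calibration, not transferability of absolute closed-loop
numbers to any physical tank.

## Problem sizes

Default study conditions, chosen once: 1200-s batches at 4-s sampling (300
controller calls), four teaching batches for the neurofuzzy database (1200
samples), six staircase + two closed-loop batches for the neural model
(2392 supervised pairs), 100 ANFIS epochs, and up to 200 LM iterations for
the network. The full pipeline — calibration, both trainings, five
closed-loop runs and all indices — executes in a few minutes on one core.
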