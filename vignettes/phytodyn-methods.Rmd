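---
title: "Methods: from monitoring records to sparse bloom equations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from monitoring records to sparse bloom equations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(phytodyn)
```

## The modelling problem

Monthly monitoring of coastal waters yields, per station and date,
chlorophyll-a (µg/l), dissolved inorganic nitrogen and phosphorus and the
total N and P pools (µmol/l), water temperature (°C), salinity (PSU) and
Secchi depth (m). Sampling days drift from year to year, so after pooling
all years onto a day-of-year axis the data form a scattered cloud around
one mean annual cycle per blooming pattern. `phytodyn` assumes that this
mean cycle is generated by an autonomous-in-state, seasonally forced system

$$\frac{dx}{dt} = f\big(x,\; \mathrm{Temp}(t), \mathrm{Sal}(t), \mathrm{Kd}(t)\big),
\qquad x = (\text{Chl-a}, \text{DIN}, \text{DIP}, \text{totN}, \text{totP}),$$

learns $f$ nonparametrically as a neural network inside the ODE, and then
projects the learned field onto a sparse second-order polynomial so the
result can be read as growth and loss terms.

Working in log/z-scored units is essential: concentrations are lognormal-ish
and span orders of magnitude across stations, and the sparse polynomial is
interpreted in terms of *above-* or *below-average* values. The price is
that every statement is about anomalies, not absolute biomass.

## Preprocessing choices

* **Natural log** before z-scoring. The base only rescales the intermediate
  step and cancels in the z-score ordering; natural log keeps derivative
  algebra clean.
* **Sample (n−1) standard deviation**, computed from the training years
  only (2000–2018 by default) and then applied unchanged to the validation
  years — no information leaks across the split.
* **Pooling**: statistics are computed per blooming pattern over all
  stations and training years together. Per-station scaling would destroy
  cross-station pooling on the day-of-year axis.
* **Temperature shift**: water temperature can reach 0 °C and below; a
  fixed +5 °C shift (configurable) precedes the log. All eight variables,
  drivers included, use the same log/z-score recipe so the network sees
  inputs on a common scale.
* **Kd from Secchi**: `Kd = 1.32 / Secchi` (an established empirical
  conversion); records carrying either quantity are usable.
* **Missingness**: records missing any state variable or driver are
  dropped, never imputed — the count is reported. Leap day stays day 60;
  driver polynomials are smooth, so a one-day shift is negligible.

## Seasonal drivers

Temp, Sal and Kd are fitted by ordinary least squares as polynomials in
rescaled time $\tau = t/366$ (orders 5, 4, 4 by default). The monomial
basis in $\tau$ keeps the design conditioned at order 5 without resorting
to orthogonal polynomials, and the coefficients stay interpretable. No
periodicity constraint is imposed; the wrap mismatch at the year boundary
is accepted, and evaluation outside day 1–366 is an error rather than an
extrapolation.

## The network ODE and its training

* **Architecture**: 8 → 16 → 16 → 16 → 16 → 5, GELU activations, linear
  output, Glorot-uniform weights, zero biases. A fixed `output_scale`
  (default 0.02 per day) multiplies the network output: z-scored seasonal
  dynamics evolve at a few hundredths of a z-unit per day, and without the
  scale a freshly initialized network produces an O(1)/day field whose
  year-long integration diverges before training can begin. The scale is
  part of the architecture, not of the initialization, so the Glorot draw
  itself is untouched.
* **Loss**: at each observation's day of year the simulated state is read
  off the trajectory (linear interpolation between integrator nodes — no
  binning) and compared with the observed 5-vector by
  $w_\ell\,\overline{(|m|-|x|)^2} + w_a\,\overline{(1-\cos(m,x))}$ with
  $w_\ell = 0.2$, $w_a = 0.8$. The length/angle decomposition is defined on
  the state vectors themselves; pairs with a zero vector contribute zero
  angle term. An alternative reading on successive displacement vectors
  exists in the literature; the state-vector form is the contract here.
* **Integration**: training uses fixed-step RK4 (1-day step by default) on
  days 1–366; gradients are exact discrete adjoints of that computation,
  implemented in compiled code, including the gradient with respect to the
  initial state. Downstream simulation uses an adaptive solver (lsoda,
  tolerances 1e-6) — the two agree to the RK4 truncation error, which the
  test suite checks against a half-step brute-force integrator.
* **Initial state**: initialized at the mean of observations in the first
  30 days of the year and then *trained jointly with the weights*. Anchoring
  it rigidly at the early-observation mean plants a day-15 average at day 1
  and shifts the whole cycle late.
* **Optimizer**: full-batch Adam with a cosine-decayed learning rate,
  3e-2 → 3e-3 over the run (500 iterations at full profile). A constant
  1e-3 — the conventional default — underfits badly within 200–500
  full-batch iterations on the synthetic sanity case; the schedule was
  fixed on that noiseless case and not revisited. If a step produces a
  non-finite loss or the integration exceeds |x| = 1e6 the step is rejected
  and the rate is halved (logged).
* **Ensemble**: 20 members at full profile, differing only in their
  initialization seed (derived deterministically from the master seed). The
  ensemble is summarised by the pointwise mean trajectory; the
  representative member minimizes the mean squared difference to that mean,
  ties broken by the lowest index. Members whose training halts or whose
  final field is unstable are dropped with a warning; the run aborts if
  fewer than half survive.

## Sparse identification

The 45-function library is ordered: constant, the 8 linear terms in
declaration order (Chl-a, DIN, DIP, totN, totP, Temp, Sal, Kd), the 8
squares, then the 28 cross products in lexicographic pair order. For each
state equation the network-approximated derivative is regressed on the
library by LASSO (glmnet, no internal standardization so the penalty acts
on the interpretable coefficient scale, no intercept beyond the library's
constant column), followed by an unpenalized least-squares refit on the
selected support — the usual debiasing step, needed because the
coefficients are read quantitatively. Coefficients below 1e-8 snap to exact
zero so "active term" counts are well-defined. Aliased columns in the refit
are dropped with a message.

**Where the derivatives are sampled.** Along a single smooth annual
trajectory every library feature is a smooth function of the day, and the
45-column design is catastrophically collinear (condition numbers around
1e8): support recovery fails at every penalty even with exact derivatives.
The right-hand side is a *state-space* function, however, so it may be
queried off the trajectory. `sample_derivatives()` therefore jitters the
query states with seeded Gaussian noise (sd 0.25 z-units by default) around
the daily trajectory, which restores identifiability; with analytic
derivatives of the synthetic truth this yields exact support recovery and
machine-precision coefficients across the default penalty grid
(10 values, 1e-6 … 3e-4), as the acceptance suite verifies. The penalty is
selected by minimizing `sum(RSS) + κ · (active terms)`; κ (default 5e-4)
was calibrated once so the analytic-derivative oracle of the two-bloom
preset recovers its true support, ties break toward the smaller penalty.

## Interpretation

A term's instantaneous effect is the product `coefficient × basis value`;
its sign classifies it as growth (positive), loss (negative) or neutral
(zero) — note a negative coefficient times a below-average (negative)
z-score is growth. Bloom growth windows are maximal runs with Chl-a z-score
> 0 **and** fitted dChl-a/dt > 0; the derivative is the sparse model's own
reconstruction, for internal consistency, and runs shorter than 5 days are
discarded as sign flicker. Within each window every term is integrated by
the trapezoidal rule on the daily grid (signed, whole-window integrals);
terms are grouped by integral sign and each term's share is
|integral| / Σ|integral| within its group, so shares sum to one per group.
The top term per group is reported; a term within 0.01 of the top share is
listed alongside it, since near-equal contributors are ecologically
interchangeable.

## The synthetic generator

The generator exists so that every stage can be scored against a known
truth. Its defaults mirror the monitoring design: 22 "years" (19 training,
3 validation), 5 stations, 12 samples per station-year at month centres
jittered ±10 days, multiplicative lognormal noise (sd 0.1 on the log
scale), 5% single-variable missingness, and year-to-year variability as a
Gaussian perturbation (sd 0.2 z-units) of the initial state. The truth is a
15-term sparse quadratic system (DIN-driven growth with a DIN-temperature
interaction, linear and quadratic chlorophyll losses, temperature-forced
nutrient cycles) whose Chl-a peaks near day 67 and day 246 and stays within
about ±1.3 z-units; "raw" records are produced by inverting a fixed
synthetic transform spec, so preprocessing is exercised end to end.

What it does **not** emulate: station heterogeneity beyond shared-year
initial conditions, autocorrelated measurement error, trends across years,
hydrodynamic transport, or zooplankton. Passing tests therefore demonstrate
correctness of the machinery under idealized monitoring statistics, not
fidelity on real coastal data.

**Scoring frame.** Preprocessing re-estimates means and standard deviations
from the generated sample, so the standardized space the models live in is
a per-variable affine image of the generator's z-space. Recovery is
scored after mapping the truth through that affine change of variables
(`truth_in_data_space()`); peak days are invariant, and the mapped
coefficient support equals the original plus the lower-order sub-monomials
the shifts introduce.

## Known limitations

Two identifiability limits surfaced by the synthetic battery deserve
emphasis, because they apply equally to real monitoring data:

1. **Driver attribution is unidentified along a mean cycle.** The three
   drivers are near-single-harmonic annual curves, hence nearly linearly
   dependent as functions of day-of-year. A model trained against one
   pooled mean trajectory can distribute its dependence arbitrarily among
   Temp, Sal, Kd (and their products) without changing the fit; the sparse
   projection inherits that arbitrariness. The acceptance suite measures
   this directly: with exact analytic derivatives the support is recovered
   exactly, while the same regression on the trained network's field
   recruits spurious driver terms.
2. **Slow equations are under-constrained.** The nutrient pools evolve at
   ~0.01–0.02 z-units/day; a trajectory fitted to within observation noise
   can carry derivative errors of that same order, so the network's field
   for those equations is only loosely pinned even on the trajectory.
   Flat-topped blooms likewise make the peak-day argmax ill-conditioned.

Denser sampling, multiple trajectories (per-year fits), or constraining the
network toward the library space would all tighten these; they are outside
the present scope.

## Problem sizes in the test suite

The unit and acceptance tests run a scaled profile — two hidden layers of
16, 200 iterations, 5 ensemble members, and the default 22-year / 5-station
generator — chosen as the smallest configuration on which the training
dynamics are representative; the full profile (4 × 16, 500 iterations, 20
members) is exercised through the same code paths with configuration only.
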