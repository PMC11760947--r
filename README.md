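# phytodyn

Learning interpretable governing equations for phytoplankton bloom dynamics
from scattered coastal monitoring data.

Coastal monitoring programmes measure chlorophyll-a (Chl-a, a biomass
proxy), dissolved inorganic nitrogen and phosphorus (DIN, DIP), total N and
P, water temperature, salinity and Secchi depth roughly once a month, at
irregular days, across many stations and years. `phytodyn` turns such
records into a dynamical description of the annual bloom cycle:

1. **Preprocessing** — records are log-transformed, z-scored with
   statistics from the training years (2000–2018 by default; 2019–2021 held
   out for validation), pooled onto a day-of-year axis, and light
   attenuation is derived from Secchi depth as `Kd = 1.32 / Secchi`.
2. **Seasonal drivers** — mean annual cycles of temperature, salinity and
   Kd are fitted as polynomials in day-of-year (orders 5, 4, 4).
3. **Neural-network ODE** — a small multilayer perceptron (8 inputs: 5
   states + 3 drivers; four hidden GELU layers of 16; 5 outputs; Glorot
   initialization) serves as the right-hand side of

   `dx/dt = ANN(x, Temp(t), Sal(t), Kd(t))`,   x = (Chl-a, DIN, DIP, totN, totP),

   trained for 500 full-batch iterations against the pooled observations
   with a trajectory loss
   `0.2 · mean((|m_i| − |x_i|)²) + 0.8 · mean(1 − cos(m_i, x_i))`
   comparing simulated and observed state vectors at each observation's
   day. Gradients are exact discrete adjoints through a fixed-step RK4
   integrator (compiled kernel). An ensemble of 20 such models is summarised
   by its pointwise mean trajectory; the member closest to the mean (smallest
   MSE) is the representative model.
4. **Sparse equation discovery (SInDy)** — the representative network is
   queried for time derivatives at states around its own trajectory, and
   each state equation is regressed on a 45-function second-order
   polynomial library (constant, 8 linear, 8 squares, 28 cross products)
   with an L1 penalty followed by an unpenalized refit on the selected
   support:

   `dChl-a/dt = c₁ + c₂·Chl-a + c₃·Chl-a² + c₄·DIN + c₅·Chl-a·DIN + … + c₄₅·Kd²`

5. **Interpretation** — each active `cᵢ·fᵢ(x, d)` product is classified as
   a growth or loss term by its overall sign (a negative coefficient times
   a below-average, negative z-score is growth), and terms are ranked by
   their integrated contribution over bloom growth windows (periods where
   the Chl-a z-score is positive and increasing).
6. **Baseline and metrics** — a penalized cyclic cubic spline over
   day-of-year provides a descriptive seasonal curve, and fit quality is
   reported as `MSE = (1/N) Σ (mᵢ − xᵢ)²` against data, or between two
   model curves on a common grid.

A synthetic-data module generates monitoring-like datasets (monthly
sampling with day jitter, multiplicative lognormal noise, random
single-variable missingness, year-to-year initial-state variability) from a
known 15-term sparse system whose Chl-a shows a spring and a late-summer
bloom, so every stage can be tested against a ground truth.

## Worked example

The whole chain on the synthetic two-bloom preset, scaled down:

```r
library(phytodyn)

cfg <- load_config()
cfg$hidden <- c(16, 16)   # scaled profile; the full profile uses 4 x 16
cfg$iterations <- 200
cfg$n_members <- 5
cfg$seed <- 1L
cfg$outdir <- "phytodyn_out"
manifest <- run_pipeline(cfg)

readLines(file.path(cfg$outdir, "equations.txt"))[1]
read.csv(file.path(cfg$outdir, "metrics.csv"))
head(read.csv(file.path(cfg$outdir, "contribution_ranking.csv")))
```

which prints (seed 1):

```
dchla/dt = 0.00818606*din + 0.00480725*totp + -0.000375317*kd + -0.00339412*din^2
         + -0.014524*kd^2 + -0.000556022*chla*din + -0.00278148*chla*totn
         + 0.00154844*chla*kd + 0.0155214*din*kd + 0.00135432*dip*totp
         + 0.0073752*dip*kd + -0.00508375*totn*totp + -0.0044214*totn*temp
         + -0.00142299*totn*kd

    pattern      comparison       mse
1 two_bloom  train_ude_mean 0.2592119
2 two_bloom  train_baseline 0.1262055
3 two_bloom baseline_vs_ude 0.1121399
4 two_bloom  valid_ude_mean 0.2687588
5 two_bloom  valid_baseline 0.1227312

    pattern window start end    group      term proportion
3 two_bloom      1    44  85 negative     din^2 0.53554030
1 two_bloom      1    44  85 positive       din 0.38095764
2 two_bloom      1    44  85 positive    din*kd 0.29081734
```

Reading the output: the discovered Chl-a equation is dominated by DIN terms
(the preset's true growth mechanism); the ensemble mean tracks the training
data with MSE 0.26 in z-units², close to the cyclic-spline baseline (0.13),
and the two curves agree to 0.11; during the spring growth window (days
44–85) the linear DIN term is the strongest positive contributor (38% of
positive contributions) and quadratic DIN the strongest negative one. Note
that sparse regression on a network-approximated vector field redistributes
weight among collinear inputs (here Kd terms absorb part of the temperature
forcing) — see the methods vignette for the identifiability discussion.

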