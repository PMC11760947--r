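Package: phytodyn
Title: Data-Driven Governing Equations for Phytoplankton Bloom Dynamics
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Learns a differential-equation representation of coupled
    chlorophyll-a and nutrient dynamics (DIN, DIP, total N, total P) from
    scattered monthly monitoring data under temperature, salinity and light
    forcing. A small neural network serves as the right-hand side of a
    five-variable ODE (a universal differential equation) trained against
    pooled day-of-year observations with a trajectory loss combining vector
    length and angle differences; an ensemble of trained models is summarised
    by its mean trajectory and a representative member. Sparse identification
    of nonlinear dynamics (SInDy) with a second-order polynomial library and
    an L1 penalty then extracts interpretable governing equations, whose
    terms are classified as growth or loss contributions and ranked over
    bloom growth windows. Includes a synthetic monitoring-data generator with
    a known sparse ground truth, a cyclic-spline seasonal baseline, and an
    end-to-end pipeline.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    deSolve,
    glmnet,
    mgcv,
    pracma,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp, RcppArmadillo
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
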