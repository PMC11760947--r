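# Synthetic monitoring-data generator.
#
# A known sparse polynomial system over the 5 z-scored state variables,
# forced by polynomial seasonal drivers, plays the role of ground truth. It
# is simulated per "year" (with a small random perturbation of the initial
# state, mimicking year-to-year variability), sampled roughly monthly at
# irregular day-of-year offsets per station, back-transformed to raw
# measurement scales through a fixed synthetic transform spec, corrupted
# with multiplicative lognormal noise, and thinned by random single-variable
# missingness — so the whole preprocessing-to-SInDy chain can be exercised
# and scored against the generating coefficients.

#' Construct a ground-truth system
#'
#' @param coef 5 x 45 coefficient matrix over the second-order library
#'   (rows: chla, din, dip, totn, totp).
#' @param drivers a `driver_set` (the polynomials are the true forcing).
#' @param x0 initial 5-vector (z-space) at day 1.
#' @param tspec synthetic `transform_spec` mapping z-space to raw scales.
#' @param noise_sd lognormal observation noise sd (log scale).
#' @param missing_rate probability that a record loses one state variable.
#' @param n_years,n_stations sampling design (years run 2000 onward).
#' @param init_sd sd of the per-year Gaussian perturbation of `x0`.
#' @param seed master seed for data generation.
#' @param name preset label, used as the blooming-pattern label.
#' @return object of class `ground_truth`.
#' @export
ground_truth_system <- function(coef, drivers, x0, tspec,
                                noise_sd = 0.1, missing_rate = 0.05,
                                n_years = 22, n_stations = 5,
                                init_sd = 0.2, seed = 1,
                                name = "synthetic") {
  library <- build_library()
  stopifnot(nrow(coef) == 5, ncol(coef) == length(library$names),
            noise_sd >= 0, missing_rate >= 0, missing_rate <= 1)
  dimnames(coef) <- list(STATE_VARS, library$names)
  structure(list(coef = coef, drivers = drivers, x0 = x0, tspec = tspec,
                 noise_sd = noise_sd, missing_rate = missing_rate,
                 n_years = n_years, n_stations = n_stations,
                 init_sd = init_sd, seed = as.integer(seed),
                 name = name, library = library),
            class = "ground_truth")
}

#' The two-bloom synthetic preset
#'
#' A 15-term sparse system whose chlorophyll-a trajectory shows a spring
#' peak (around day 67) and a late-summer peak (around day 246): nutrient
#' (DIN) linear and quadratic growth terms with a DIN-temperature
#' interaction, a linear and a quadratic chlorophyll loss, DIN forced by
#' temperature with uptake by chlorophyll, and first-order seasonal dynamics
#' for DIP, totN and totP. Drivers are polynomial fits (orders 5/4/4) of
#' smooth annual cycles. The nonzero support is attached as attribute
#' `support` of the coefficient matrix.
#'
#' @param seed master seed used for subsequent data generation.
#' @param noise_sd,missing_rate,n_years,n_stations,init_sd overrides of the
#'   default study conditions (22 years, 5 stations, lognormal noise sd 0.1,
#'   5% single-variable missingness, 0.2 initial-state spread).
#' @return a `ground_truth` system.
#' @export
make_two_bloom_preset <- function(seed = 1, noise_sd = 0.1, missing_rate = 0.05,
                                  n_years = 22, n_stations = 5, init_sd = 0.2) {
  t <- 1:366
  cycles <- list(
    temp = list(y = 1.35 * -cos(2 * pi * (t - 15) / 365), order = 5),
    sal  = list(y = 0.70 * cos(2 * pi * (t - 40) / 365), order = 4),
    kd   = list(y = 0.90 * cos(2 * pi * (t - 355) / 365), order = 4)
  )
  models <- lapply(names(cycles), function(v)
    fit_driver_polynomial(t, cycles[[v]]$y, cycles[[v]]$order, variable = v))
  names(models) <- names(cycles)
  drivers <- structure(models, class = "driver_set")

  library <- build_library()
  cf <- matrix(0, 5, length(library$names),
               dimnames = list(STATE_VARS, library$names))
  set_term <- function(eq, term, value) cf[eq, term] <<- value
  set_term("chla", "din", 0.015)
  set_term("chla", "temp", 0.02)
  set_term("chla", "din^2", 0.07)
  set_term("chla", "din*temp", 0.02)
  set_term("chla", "chla^2", -0.012)   # density-dependent (quadratic) loss
  set_term("chla", "chla", -0.06)
  set_term("din", "chla*din", -0.01)   # uptake by the bloom
  set_term("din", "temp", -0.02)
  set_term("din", "din", -0.015)
  set_term("dip", "temp", -0.025)
  set_term("dip", "dip", -0.05)
  set_term("totn", "totn", -0.02)
  set_term("totn", "temp", -0.01)
  set_term("totp", "chla", 0.02)
  set_term("totp", "totp", -0.03)
  attr(cf, "support") <- which(cf != 0, arr.ind = TRUE)

  tspec <- structure(list(
    mean = list(chla = log(5), din = log(6), dip = log(0.5),
                totn = log(35), totp = log(1.2),
                temp = log(15), sal = log(10), kd = log(0.8)),
    sd = list(chla = 0.9, din = 1.1, dip = 0.8, totn = 0.35, totp = 0.45,
              temp = 0.45, sal = 0.15, kd = 0.5),
    temp_shift = DEFAULT_TEMP_SHIFT), class = "transform_spec")

  ground_truth_system(cf, drivers, x0 = c(-0.8, 0.8, 0.6, 0.6, -0.3),
                      tspec = tspec, noise_sd = noise_sd,
                      missing_rate = missing_rate, n_years = n_years,
                      n_stations = n_stations, init_sd = init_sd,
                      seed = seed, name = "two_bloom")
}

# Right-hand side of the sparse polynomial truth at state x, day t.
truth_rhs_at <- function(system, x, t) {
  d <- evaluate_drivers(system$drivers, t)
  as.numeric(system$coef %*% evaluate_library(system$library, x, d))
}

#' Simulate the ground-truth system
#'
#' Adaptive integration (lsoda, tolerance 1e-8) of the sparse polynomial
#' system under its driver forcing.
#'
#' @param system a `ground_truth`.
#' @param t_grid increasing days within \[1, 366\].
#' @param x0 initial state (default the system's).
#' @return length(t_grid) x 5 matrix of z-space states.
#' @export
simulate_truth <- function(system, t_grid = 1:366, x0 = system$x0) {
  stopifnot(inherits(system, "ground_truth"))
  if (is.unsorted(t_grid, strictly = TRUE)) stop("t_grid must be increasing")
  if (t_grid[1] < 1 || t_grid[length(t_grid)] > 366) stop("t_grid outside [1, 366]")
  # lsoda may probe marginally outside the requested span; clamp to the
  # driver domain (the polynomials are smooth there).
  rhs <- function(t, y, p) list(truth_rhs_at(system, y, min(max(t, 1), 366)))
  sol <- suppressWarnings(
    deSolve::ode(y = as.numeric(x0), times = t_grid, func = rhs, parms = NULL,
                 method = "lsoda", rtol = 1e-8, atol = 1e-8))
  X <- unname(sol[, -1, drop = FALSE])
  if (nrow(X) < length(t_grid) || any(!is.finite(X)) || max(abs(X)) > 1e6)
    stop("ground-truth simulation of preset '", system$name,
         "' is unstable (|x| > 1e6)")
  colnames(X) <- STATE_VARS
  X
}

#' Analytic derivative samples of the truth system
#'
#' Evaluates the true polynomial right-hand side at states on (or jittered
#' around) the truth trajectory — the exact-recovery oracle for
#' [fit_sparse()].
#'
#' @param system a `ground_truth`.
#' @param t_grid day grid.
#' @param jitter_sd state jitter sd (see [sample_derivatives()]).
#' @param seed jitter seed.
#' @return a `derivative_sample`.
#' @export
truth_derivatives <- function(system, t_grid = 1:366, jitter_sd = 0.25, seed = 1) {
  X <- simulate_truth(system, t_grid)
  if (jitter_sd > 0)
    X <- X + with_seed(seed, matrix(rnorm(length(X), 0, jitter_sd), nrow(X)))
  D <- evaluate_drivers(system$drivers, t_grid)
  Theta <- evaluate_library(system$library, X, D)
  Xdot <- Theta %*% t(system$coef)
  colnames(Xdot) <- STATE_VARS
  derivative_sample(t_grid, X, D, Xdot)
}

# Sampling days: one per month at the month centre plus uniform jitter of
# up to +-10 days, clamped to [1, 365].
month_centers <- c(15, 46, 74, 105, 135, 166, 196, 227, 258, 288, 319, 349)

#' Sample monitoring-like records from a dense yearly trajectory
#'
#' For each station, draws 12 samples at jittered month centres, reads
#' states off the trajectory and drivers off the driver polynomials,
#' back-transforms z-scores to raw measurement scales, applies
#' multiplicative lognormal noise, and blanks one state variable per record
#' with probability `missing_rate`. Secchi depth (not Kd) is emitted, as in
#' field campaigns.
#'
#' @param trajectory matrix from [simulate_truth()] covering days 1..366.
#' @param system the generating `ground_truth`.
#' @param year calendar year label for the records.
#' @param seed seed for sampling days, noise and missingness.
#' @return data frame of raw records (one row per station-date).
#' @export
sample_monitoring <- function(trajectory, system, year = 2000, seed = system$seed) {
  stopifnot(inherits(system, "ground_truth"), nrow(trajectory) >= 366)
  with_seed(seed, {
    recs <- list()
    for (s in seq_len(system$n_stations)) {
      days <- pmin(pmax(round(month_centers +
                                runif(12, -10, 10)), 1), 365)
      z <- as.data.frame(trajectory[days, , drop = FALSE])
      D <- evaluate_drivers(system$drivers, days)
      z$temp <- D[, "temp"]; z$sal <- D[, "sal"]; z$kd <- D[, "kd"]
      raw <- invert_zscore(z, system$tspec)
      if (system$noise_sd > 0) {
        for (v in ALL_VARS) {
          noise <- exp(rnorm(12, 0, system$noise_sd))
          if (v == "temp") {
            raw[[v]] <- (raw[[v]] + system$tspec$temp_shift) * noise -
              system$tspec$temp_shift
          } else {
            raw[[v]] <- raw[[v]] * noise
          }
        }
      }
      if (system$missing_rate > 0) {
        drop <- runif(12) < system$missing_rate
        which_var <- sample(STATE_VARS, 12, replace = TRUE)
        for (k in which(drop)) raw[[which_var[k]]][k] <- NA_real_
      }
      recs[[s]] <- data.frame(
        station_id = sprintf("S%02d", s),
        date = as.character(as.Date(days - 1, origin = paste0(year, "-01-01"))),
        chla = raw$chla, din = raw$din, dip = raw$dip,
        totn = raw$totn, totp = raw$totp,
        temp = raw$temp, sal = raw$sal,
        secchi = 1.32 / raw$kd,
        pattern = system$name,
        stringsAsFactors = FALSE
      )
    }
    do.call(rbind, recs)
  })
}

#' Generate a full multi-year synthetic monitoring dataset
#'
#' Years run from `first_year` for `n_years`; each year's trajectory starts
#' from the preset initial state plus a Gaussian perturbation (sd
#' `init_sd`), then [sample_monitoring()] is applied. Fully reproducible
#' from the system's seed.
#'
#' @param system a `ground_truth`.
#' @param first_year first calendar year (default 2000, so the default
#'   22-year run covers the 2000-2018 / 2019-2021 split).
#' @return list with `records` (raw data frame) and `system`.
#' @export
generate_monitoring <- function(system, first_year = 2000) {
  stopifnot(inherits(system, "ground_truth"))
  years <- first_year + seq_len(system$n_years) - 1L
  year_seeds <- with_seed(system$seed, sample.int(2^30, system$n_years + 1L))
  perturb <- with_seed(year_seeds[system$n_years + 1L],
                       matrix(rnorm(5 * system$n_years, 0, system$init_sd),
                              ncol = 5))
  records <- list()
  for (k in seq_along(years)) {
    x0 <- system$x0 + perturb[k, ]
    traj <- simulate_truth(system, 1:366, x0 = x0)
    records[[k]] <- sample_monitoring(traj, system, year = years[k],
                                      seed = year_seeds[k])
  }
  list(records = do.call(rbind, records), system = system)
}

#' Transform a sparse coefficient matrix under per-variable affine maps
#'
#' Rewrites the polynomial system `dx_i/dt = sum c_T prod z_k^(e_k)` in new
#' coordinates `z'_k = scale_k * z_k + shift_k` (so each old variable is
#' `(z'_k - shift_k)/scale_k` and each derivative picks up `scale_i`).
#' Used to express the generator's ground-truth support in the coordinate
#' frame that preprocessing actually fits from the sample, where recovery
#' can be scored honestly: the transformed support is the original one plus
#' the lower-order sub-monomials introduced by nonzero shifts.
#'
#' @param coef equations x 45 coefficient matrix.
#' @param library the `basis_library`.
#' @param scale,shift numeric vectors over the library variables (length 8:
#'   5 states then 3 drivers).
#' @return the transformed coefficient matrix (entries below 1e-12 snapped
#'   to zero).
#' @export
affine_transform_coef <- function(coef, library, scale, shift) {
  stopifnot(inherits(library, "basis_library"),
            length(scale) == length(library$vars),
            length(shift) == length(library$vars))
  nv <- length(library$vars)
  term_index <- function(e) {
    hit <- which(vapply(library$terms, function(f) all(f == e), logical(1)))
    if (length(hit) != 1) stop("monomial outside library order")
    hit
  }
  out <- matrix(0, nrow(coef), ncol(coef), dimnames = dimnames(coef))
  for (i in seq_len(nrow(coef))) {
    for (j in which(coef[i, ] != 0)) {
      e <- library$terms[[j]]
      # expand prod_k ((z'_k - shift_k)/scale_k)^(e_k) as a polynomial in z'
      expansion <- list(list(e = integer(nv), c = 1))
      for (k in which(e > 0L)) for (rep in seq_len(e[k])) {
        expansion <- do.call(c, lapply(expansion, function(p) {
          e1 <- p$e; e1[k] <- e1[k] + 1L
          list(list(e = e1, c = p$c / scale[k]),
               list(e = p$e, c = -p$c * shift[k] / scale[k]))
        }))
      }
      for (p in expansion) {
        idx <- term_index(p$e)
        out[i, idx] <- out[i, idx] + scale[i] * coef[i, j] * p$c
      }
    }
  }
  out[abs(out) < 1e-12] <- 0
  out
}

#' Express the ground truth in a fitted standardized coordinate frame
#'
#' Preprocessing re-estimates means and standard deviations from the
#' sample, so the standardized space downstream models live in is a
#' per-variable affine image of the generator's z-space. This helper
#' computes the affine map between the two frames and returns the truth
#' coefficient matrix and trajectory mapped into the fitted frame.
#'
#' @param system a `ground_truth`.
#' @param tspec_fit the `transform_spec` fitted from the generated sample.
#' @return list: `scale`, `shift` (length 8), `coef` (transformed 5 x 45
#'   matrix), `map_states(X)` mapping a generator-frame state matrix into
#'   the fitted frame.
#' @export
truth_in_data_space <- function(system, tspec_fit) {
  stopifnot(inherits(system, "ground_truth"), inherits(tspec_fit, "transform_spec"))
  vars <- system$library$vars
  scale <- vapply(vars, function(v) system$tspec$sd[[v]] / tspec_fit$sd[[v]], 1)
  shift <- vapply(vars, function(v)
    (system$tspec$mean[[v]] - tspec_fit$mean[[v]]) / tspec_fit$sd[[v]], 1)
  coef <- affine_transform_coef(system$coef, system$library, scale, shift)
  map_states <- function(X)
    sweep(sweep(X, 2, scale[seq_len(ncol(X))], `*`), 2,
          shift[seq_len(ncol(X))], `+`)
  list(scale = scale, shift = shift, coef = coef, map_states = map_states)
}
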