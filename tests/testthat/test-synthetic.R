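test_that("the all-zero system stays at its initial state", {
  sys <- get_preset()
  zero <- ground_truth_system(matrix(0, 5, 45), sys$drivers,
                              x0 = c(0.5, -0.2, 0.1, 0, 1), tspec = sys$tspec)
  X <- simulate_truth(zero, c(1, 100, 366))
  for (i in 1:3) expect_equal(unname(X[i, ]), c(0.5, -0.2, 0.1, 0, 1),
                              tolerance = 1e-8)
})

test_that("a pure linear decay integrates to the closed form", {
  sys <- get_preset()
  cf <- matrix(0, 5, 45, dimnames = list(NULL, build_library()$names))
  cf[1, "chla"] <- -1   # dchla/dt = -chla, per day
  dec <- ground_truth_system(cf, sys$drivers, x0 = c(1, 0, 0, 0, 0),
                             tspec = sys$tspec)
  X <- simulate_truth(dec, c(1, 2))
  expect_equal(unname(X[2, "chla"]), exp(-1), tolerance = 1e-6)
})

test_that("the two-bloom preset has exactly two positive chlorophyll peaks", {
  y <- get_truth_traj()[, "chla"]
  pk <- peak_days(y)
  expect_length(pk, 2)
  expect_gt(pk[1], 30); expect_lt(pk[1], 140)   # spring
  expect_gt(pk[2], 180); expect_lt(pk[2], 300)  # late summer
  expect_true(all(abs(get_truth_traj()) < 4))
  sup <- attr(get_preset()$coef, "support")
  expect_equal(nrow(sup), 15)
  expect_true(all(table(sup[, 1]) <= 12))
})

test_that("removing the quadratic chlorophyll loss raises the peak", {
  sys <- get_preset()
  sys2 <- sys
  sys2$coef["chla", "chla^2"] <- 0
  base <- max(get_truth_traj()[, "chla"])
  expect_gt(max(simulate_truth(sys2)[, "chla"]), base)
})

test_that("an unstable system raises an instability error naming the preset", {
  sys <- get_preset()
  cf <- matrix(0, 5, 45, dimnames = list(NULL, build_library()$names))
  cf[1, "chla"] <- 0.5   # exponential blow-up within the year
  bad <- ground_truth_system(cf, sys$drivers, x0 = c(1, 0, 0, 0, 0),
                             tspec = sys$tspec, name = "runaway")
  expect_error(simulate_truth(bad), "runaway")
})

test_that("sampling is exact without noise and reproducible under a seed", {
  sys <- make_two_bloom_preset(seed = 7, noise_sd = 0, missing_rate = 0,
                               n_years = 2, n_stations = 2)
  traj <- simulate_truth(sys)
  rec <- sample_monitoring(traj, sys, year = 2000)
  expect_equal(nrow(rec), 2 * 12)
  # back-transform through the generator spec must land on the trajectory
  z <- log_zscore(rec, sys$tspec)
  days <- z$day_of_year
  expect_equal(z$chla, traj[days, "chla"], tolerance = 1e-10)
  expect_equal(z$din, traj[days, "din"], tolerance = 1e-10)
  expect_equal(z$kd, unname(evaluate_drivers(sys$drivers, days)[, "kd"]),
               tolerance = 1e-10)
  rec2 <- sample_monitoring(traj, sys, year = 2000)
  expect_identical(rec, rec2)
})

test_that("dataset size and missingness follow the design", {
  sys <- make_two_bloom_preset(seed = 3, noise_sd = 0, missing_rate = 0,
                               n_years = 22, n_stations = 5)
  ds <- generate_monitoring(sys)
  expect_equal(nrow(ds$records), 22 * 5 * 12)
  expect_true(all(!is.na(ds$records$chla)))
  expect_identical(generate_monitoring(sys)$records, ds$records)

  all_missing <- make_two_bloom_preset(seed = 3, missing_rate = 1,
                                       n_years = 1, n_stations = 2)
  ds2 <- generate_monitoring(all_missing)
  expect_warning(out <- suppressMessages(drop_incomplete(ds2$records)), "no complete")
  expect_equal(nrow(out), 0)
})

test_that("empirical lognormal noise sd matches the configured sd", {
  sys <- make_two_bloom_preset(seed = 5, noise_sd = 0.2, missing_rate = 0,
                               n_years = 20, n_stations = 10, init_sd = 0)
  ds <- generate_monitoring(sys)
  traj <- simulate_truth(sys)
  z <- log_zscore(ds$records, sys$tspec)
  # log-scale residual of chla against the exact trajectory = noise draw
  resid <- (z$chla - traj[z$day_of_year, "chla"]) * sys$tspec$sd$chla
  expect_lt(abs(sd(resid) - 0.2) / 0.2, 0.05)
})

test_that("affine change of variables maps supports as expected", {
  lib <- build_library()
  sys <- get_preset()
  cf0 <- sys$coef; attr(cf0, "support") <- NULL
  # identity map leaves coefficients untouched
  id <- affine_transform_coef(cf0, lib, rep(1, 8), rep(0, 8))
  expect_equal(unname(id), unname(cf0))
  # pure scaling keeps the support identical
  sc <- affine_transform_coef(sys$coef, lib, rep(2, 8), rep(0, 8))
  expect_equal(unname(sc != 0), unname(sys$coef != 0))
  # shifts add only lower-order terms, never remove originals
  sh <- affine_transform_coef(sys$coef, lib, rep(1.5, 8), rep(-0.3, 8))
  expect_true(all(sh[sys$coef != 0] != 0))
  # round trip through the inverse map restores the matrix
  a <- seq(0.5, 4, length.out = 8); b <- seq(-0.5, 0.5, length.out = 8)
  fwd <- affine_transform_coef(cf0, lib, a, b)
  back <- affine_transform_coef(fwd, lib, 1 / a, -b / a)
  expect_equal(unname(back), unname(cf0), tolerance = 1e-10)
})

test_that("analytic truth derivatives satisfy the generating equations", {
  sys <- get_preset()
  s <- truth_derivatives(sys, t_grid = seq(1, 366, by = 10), jitter_sd = 0.3,
                         seed = 2)
  Theta <- evaluate_library(sys$library, s$X, s$D)
  expect_equal(unname(s$Xdot), unname(Theta %*% t(sys$coef)), tolerance = 1e-12)
})
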