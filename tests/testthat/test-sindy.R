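test_that("library size follows 1 + n + n(n+1)/2 and ordering is fixed", {
  lib <- build_library()
  expect_length(lib$names, 45)
  expect_equal(lib$names[1], "1")
  expect_equal(lib$names[2:9],
               c("chla", "din", "dip", "totn", "totp", "temp", "sal", "kd"))
  expect_equal(lib$names[10], "chla^2")
  expect_equal(lib$names[18], "chla*din")
  expect_false(any(duplicated(lib$names)))
  expect_length(build_library("x", character(0))$names, 3)
  expect_length(build_library(c("x", "y", "z"), character(0))$names, 10)
  for (n in 1:10) {
    vars <- paste0("v", seq_len(n))
    expect_length(build_library(vars, character(0))$names, 1 + n + n * (n + 1) / 2)
  }
  expect_error(build_library(order = 3), "order")
})

test_that("library evaluation matches brute-force monomial products", {
  lib <- build_library()
  z <- evaluate_library(lib, rep(0, 5), rep(0, 3))
  expect_equal(unname(z[1]), 1)
  expect_true(all(z[-1] == 0))
  v <- evaluate_library(lib, c(2, 0, 0, 0, 0), rep(0, 3))
  expect_equal(unname(v[c("chla", "chla^2")]), c(2, 4))
  expect_true(all(v[grep("chla\\*", names(v))] == 0))
  set.seed(4)
  for (k in 1:5) {
    x <- rnorm(5); d <- rnorm(3); u <- c(x, d)
    got <- evaluate_library(lib, x, d)
    brute <- vapply(lib$terms, function(e) prod(u^e), 1)
    expect_equal(unname(got), brute, tolerance = 1e-12)
  }
})

test_that("unpenalized fit equals ordinary least squares", {
  set.seed(11)
  lib <- build_library()
  n <- 120
  X <- matrix(rnorm(n * 5), n); D <- matrix(rnorm(n * 3), n)
  Theta <- evaluate_library(lib, X, D)
  beta <- rep(0, 45); beta[c(1, 3, 17, 30)] <- c(0.5, -1, 2, 0.3)
  Xdot <- cbind(Theta %*% beta + rnorm(n, 0, 0.01),
                matrix(0, n, 4))
  colnames(Xdot) <- c("chla", "din", "dip", "totn", "totp")
  s <- derivative_sample(seq_len(n), X, D, Xdot)
  fit <- fit_sparse(s, lib, penalty = 0)
  ols <- qr.coef(qr(Theta), Xdot[, 1])
  expect_equal(unname(fit$coef[1, ]), unname(ols), tolerance = 1e-8)
  # an identically-zero derivative stays all-zero with zero residual
  expect_true(all(fit$coef[2, ] == 0))
  expect_equal(fit$rss[2], 0)
})

test_that("exact support recovery from analytic derivatives of the preset", {
  sys <- get_preset()
  lib <- sys$library
  s <- truth_derivatives(sys, jitter_sd = 0.25, seed = 1)
  fit <- fit_sparse(s, lib, penalty = 1e-5)
  expect_equal(unname(fit$coef != 0), unname(sys$coef != 0))
  expect_lt(max(abs(fit$coef - sys$coef)), 1e-6)
})

test_that("penalty tuning selects from the documented criterion", {
  sys <- get_preset()
  lib <- sys$library
  s <- truth_derivatives(sys, jitter_sd = 0.25, seed = 1)
  single <- tune_sparsity(s, lib, penalty_grid = 3e-5)
  expect_equal(as.numeric(single), 3e-5)
  grid <- 10^seq(-6, log10(3e-4), length.out = 10)
  best <- tune_sparsity(s, lib, grid)
  # brute-force scan: the tuned penalty must lie in the exact-recovery range
  ok <- vapply(grid, function(lam) {
    f <- fit_sparse(s, lib, lam)
    identical(unname(f$coef != 0), unname(sys$coef != 0))
  }, logical(1))
  expect_true(ok[match(as.numeric(best), grid)])
  # kappa = 0 reduces to residual minimization: smallest penalty wins
  expect_equal(as.numeric(tune_sparsity(s, lib, c(1e-4, 1e-3, 1e-2), kappa = 0)),
               1e-4)
})

test_that("residuals are monotone in the penalty on a fixed sample", {
  sys <- get_preset()
  s <- truth_derivatives(sys, t_grid = seq(1, 366, by = 4), jitter_sd = 0.25,
                         seed = 3)
  s$Xdot <- s$Xdot + matrix(rnorm(length(s$Xdot), 0, 0.005), nrow(s$Xdot))
  rss <- vapply(c(1e-5, 1e-4, 1e-3, 1e-2), function(lam)
    sum(fit_sparse(s, sys$library, lam)$rss), 1)
  expect_true(all(diff(rss) >= -1e-10))
})

test_that("equation text round-trips through the parser", {
  sys <- get_preset()
  lib <- sys$library
  s <- truth_derivatives(sys, jitter_sd = 0.25, seed = 1)
  fit <- fit_sparse(s, lib, penalty = 1e-5)
  lines <- to_equations(fit)
  expect_length(lines, 5)
  back <- parse_equations(lines, lib)
  expect_equal(unname(back), unname(fit$coef), tolerance = 1e-5)
  # degenerate cases
  zero <- fit; zero$coef[] <- 0
  expect_equal(to_equations(zero), paste0("d", rownames(fit$coef), "/dt = 0"))
  one <- zero; one$coef[1, 1] <- 0.5
  expect_equal(to_equations(one)[1], "dchla/dt = 0.5")
  expect_equal(parse_equations(to_equations(one), lib)[1, 1], 0.5)
})

test_that("derivative harvesting matches finite differences of the simulation", {
  sys <- get_preset()
  spec <- network_spec(hidden = c(8, 8), seed = 21)
  m <- init_network(spec, sys$drivers)
  s <- sample_derivatives(m, sys$drivers, t_grid = 50:150, jitter_sd = 0)
  expect_equal(nrow(s$X), 101)
  # central differences of a dense simulation approximate the sampled field
  dense <- simulate_ude(m, s$X[1, ], seq(50, 150, by = 0.5), sys$drivers,
                        rtol = 1e-10, atol = 1e-10)
  fd <- (dense[seq(3, 201, 2), ] - dense[seq(1, 199, 2), ]) / 1
  expect_lt(max(abs(s$Xdot[2:100, ] - fd[1:99, ])), 1e-3)
  # a zeroed final layer yields a zero field and a constant state
  m0 <- m; m0$params$W[[3]][] <- 0; m0$params$b[[3]][] <- 0
  s0 <- sample_derivatives(m0, sys$drivers, t_grid = 1:50, jitter_sd = 0)
  expect_true(all(s0$Xdot == 0))
  expect_true(all(abs(sweep(s0$X, 2, s0$X[1, ])) < 1e-8))
})
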