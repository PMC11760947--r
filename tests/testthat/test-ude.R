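test_that("Glorot initialization is seeded and has the documented size", {
  spec <- network_spec(hidden = c(16, 16, 16, 16), seed = 42)
  m <- init_network(spec)
  expect_equal(n_parameters(m), 1045)  # (8*16+16) + 3*(16*16+16) + (16*5+5)
  m2 <- init_network(spec)
  expect_identical(m$params, m2$params)
  spec2 <- spec; spec2$seed <- 43L
  m3 <- init_network(spec2)
  expect_false(identical(m$params$W[[1]], m3$params$W[[1]]))
  lim <- sqrt(6 / (8 + 16))
  expect_true(all(abs(m$params$W[[1]]) <= lim))
  expect_true(all(m$params$b[[1]] == 0))
})

test_that("trajectory loss identities hold", {
  a <- matrix(rnorm(20), 4)
  expect_equal(lda_loss(a, a), 0)
  # colinear vectors: angle term vanishes, only lengths differ
  expect_equal(lda_loss(a, 2 * a),
               0.2 * mean((sqrt(rowSums(a^2)) - sqrt(rowSums((2 * a)^2)))^2))
  # orthogonal unit vectors at default weights
  expect_equal(lda_loss(c(1, 0, 0, 0, 0), c(0, 1, 0, 0, 0)), 0.8)
  # zero vectors contribute nothing to the angle term
  expect_equal(lda_loss(c(0, 0, 0, 0, 0), c(1, 0, 0, 0, 0)), 0.2)
  expect_error(lda_loss(a, a[1:2, ]), "shapes")
  # nonnegativity on random pairs
  set.seed(1)
  for (k in 1:20) {
    l <- lda_loss(matrix(rnorm(15), 3), matrix(rnorm(15), 3))
    expect_gte(l, 0)
  }
})

test_that("compiled loss matches the reference implementation and its gradient", {
  sys <- get_preset()
  spec <- network_spec(hidden = c(8, 8), seed = 3)
  m <- init_network(spec, sys$drivers)
  cfg <- training_config(iterations = 1, solver_step = 2)
  series <- data.frame(day_of_year = c(20, 100, 200, 300),
                       chla = c(-0.5, 0.8, 0.2, -0.2), din = c(1, 0.5, -0.5, 0.5),
                       dip = c(0.5, 0, -0.3, 0.2), totn = c(0.5, 0.3, -0.2, 0.1),
                       totp = c(-0.3, 0, 0.3, -0.1))
  setup <- build_training_setup(series, sys$drivers, cfg)
  x0 <- initial_state(series)
  res <- cpp_ude_loss_grad(m$params$W, m$params$b, x0, setup$h,
                           setup$Dnode, setup$Dmid, setup$obs_i, setup$obs_w,
                           setup$obs, 0.2, 0.8, TRUE, spec$output_scale)
  # loss agrees with the plain-R loss on the interpolated trajectory
  sim <- (1 - setup$obs_w) * res$traj[setup$obs_i + 1, ] +
    setup$obs_w * res$traj[setup$obs_i + 2, ]
  expect_equal(res$loss, lda_loss(sim, setup$obs), tolerance = 1e-12)
  # adjoint gradient agrees with central finite differences
  theta <- c(unlist(m$params$W), unlist(m$params$b))
  g <- c(unlist(res$gradW), unlist(res$gradb))
  lossfun <- function(th) {
    W <- m$params$W; b <- m$params$b; off <- 0
    for (l in seq_along(W)) { n <- length(W[[l]]); W[[l]][] <- th[off + 1:n]; off <- off + n }
    for (l in seq_along(b)) { n <- length(b[[l]]); b[[l]][] <- th[off + 1:n]; off <- off + n }
    cpp_ude_loss_grad(W, b, x0, setup$h, setup$Dnode, setup$Dmid, setup$obs_i,
                      setup$obs_w, setup$obs, 0.2, 0.8, FALSE, spec$output_scale)$loss
  }
  set.seed(9)
  for (j in sample(length(theta), 8)) {
    tp <- theta; tp[j] <- tp[j] + 1e-6
    tm <- theta; tm[j] <- tm[j] - 1e-6
    fd <- (lossfun(tp) - lossfun(tm)) / 2e-6
    expect_equal(g[j], fd, tolerance = 1e-4)
  }
})

test_that("simulation honours degenerate networks and matches a fixed-step oracle", {
  sys <- get_preset()
  spec <- network_spec(hidden = c(8, 8), seed = 5)
  m <- init_network(spec, sys$drivers)
  # zeroed final layer: the vector field vanishes, trajectory is constant
  m0 <- m
  m0$params$W[[3]][] <- 0
  x0 <- c(0.3, -0.1, 0.2, 0, -0.4)
  X <- simulate_ude(m0, x0, c(1, 50, 180, 366), sys$drivers)
  for (i in 1:4) expect_equal(unname(X[i, ]), x0, tolerance = 1e-8)
  expect_equal(unname(simulate_ude(m, x0, c(1, 10), sys$drivers)[1, ]), x0)
  # adaptive solution vs brute-force fixed-step RK4 at two resolutions
  rk4 <- function(h) {
    t <- seq(1, 101, by = h)
    x <- x0
    f <- function(x, tt) as.numeric(mlp_eval(m$params,
      c(x, evaluate_drivers(sys$drivers, tt)), spec$output_scale))
    for (i in seq_len(length(t) - 1)) {
      k1 <- f(x, t[i]); k2 <- f(x + h / 2 * k1, t[i] + h / 2)
      k3 <- f(x + h / 2 * k2, t[i] + h / 2); k4 <- f(x + h * k3, t[i] + h)
      x <- x + h / 6 * (k1 + 2 * k2 + 2 * k3 + k4)
    }
    x
  }
  Xa <- simulate_ude(m, x0, c(1, 101), sys$drivers, rtol = 1e-10, atol = 1e-10)
  expect_equal(unname(Xa[2, ]), rk4(0.5), tolerance = 1e-4)
  expect_lt(max(abs(rk4(0.5) - rk4(0.25))), 1e-6)
})

test_that("training reduces the loss and records a finite history", {
  sys <- get_preset()
  set.seed(2)
  days <- sort(sample(5:360, 40))
  truth <- get_truth_traj()
  series <- data.frame(day_of_year = days, truth[days, , drop = FALSE])
  spec <- network_spec(hidden = c(8, 8), seed = 1)
  m0 <- train_ude(series, sys$drivers, spec,
                  training_config(iterations = 0))
  expect_identical(m0$params, init_network(spec)$params)
  expect_length(m0$loss_history, 0)
  m <- suppressMessages(train_ude(series, sys$drivers, spec,
                                  training_config(iterations = 40)))
  expect_length(m$loss_history, 40)
  expect_true(all(is.finite(m$loss_history)))
  expect_lt(tail(m$loss_history, 1), m$loss_history[1])
})

test_that("ensembles average members and pick the representative by MSE", {
  sys <- get_preset()
  set.seed(3)
  days <- sort(sample(5:360, 30))
  truth <- get_truth_traj()
  series <- data.frame(day_of_year = days, truth[days, , drop = FALSE])
  spec <- network_spec(hidden = c(8, 8), seed = 7)
  cfg <- training_config(iterations = 15)
  one <- suppressMessages(train_ensemble(series, sys$drivers, spec, cfg,
                                         n_members = 1, t_grid = seq(1, 366, 5)))
  expect_equal(one$mean_traj, one$member_traj[[1]])
  expect_equal(select_representative(one)$loss_history,
               one$members[[1]]$loss_history)

  same <- suppressMessages(train_ensemble(series, sys$drivers, spec, cfg,
                                          n_members = 3, t_grid = seq(1, 366, 5),
                                          member_seeds = c(5, 5, 5)))
  expect_equal(same$member_traj[[1]], same$member_traj[[2]])
  expect_equal(unname(same$member_mse), rep(0, 3), tolerance = 1e-20)

  ens <- suppressMessages(train_ensemble(series, sys$drivers, spec, cfg,
                                         n_members = 3, t_grid = seq(1, 366, 5)))
  expect_true(all(is.finite(ens$member_mse)) && any(ens$member_mse > 0))
  expect_equal(attr(select_representative(ens), "index"),
               which.min(ens$member_mse))
  expect_equal(ens$mean_traj, Reduce(`+`, ens$member_traj) / 3)
})
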