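# Neural-network ODE (universal differential equation) core.
#
# A small multilayer perceptron maps (5 states, 3 drivers) -> 5 time
# derivatives and is used as the right-hand side of an ODE over the
# day-of-year axis. Training minimizes a trajectory loss between the
# simulated annual trajectory, evaluated at each observation's day of year,
# and the pooled standardized observations. Gradients are exact discrete
# adjoints through a fixed-step RK4 integrator (compiled kernel); simulation
# for downstream use goes through an adaptive solver (deSolve).

#' Network architecture specification
#'
#' The reference architecture is 8 inputs (5 states + 3 drivers), four
#' hidden layers of 16 units with GELU activations, 5 linear outputs, and
#' Glorot-uniform weight initialization.
#'
#' Because the network output is a time derivative in z-units per day, and
#' seasonal z-space dynamics evolve on rates of a few hundredths per day, a
#' fixed `output_scale` multiplies the final linear layer. This keeps the
#' freshly initialized vector field on the physical time scale (a
#' Glorot-initialized network otherwise produces O(1)/day fields whose
#' year-long integration diverges before training can start).
#'
#' @param hidden integer vector of hidden-layer widths.
#' @param seed integer seed for weight initialization.
#' @param output_scale fixed multiplier on the network output (1/day).
#' @return object of class `network_spec`.
#' @export
network_spec <- function(hidden = c(16, 16, 16, 16), seed = 1,
                         output_scale = 0.02) {
  widths <- c(length(STATE_VARS) + length(DRIVER_VARS), hidden, length(STATE_VARS))
  structure(list(widths = widths, activation = "gelu",
                 initialization = "glorot", seed = as.integer(seed),
                 output_scale = output_scale),
            class = "network_spec")
}

#' Training configuration
#'
#' @param iterations full-batch gradient steps (reference value 500; the
#'   scaled test profile uses fewer).
#' @param w_length,w_angle trajectory-loss weights for the length and angle
#'   terms; must sum to 1. Reference values 0.2 / 0.8.
#' @param learning_rate initial Adam step size.
#' @param lr_final final Adam step size; the rate follows a cosine decay
#'   from `learning_rate` to `lr_final` over the iterations.
#' @param solver_step RK4 step (days) of the training integrator.
#' @param rtol,atol tolerances of the adaptive simulation solver.
#' @return object of class `training_config`.
#' @export
training_config <- function(iterations = 500, w_length = 0.2, w_angle = 0.8,
                            learning_rate = 3e-2, lr_final = 3e-3,
                            solver_step = 1, rtol = 1e-6, atol = 1e-6) {
  if (abs(w_length + w_angle - 1) > 1e-12) stop("loss weights must sum to 1")
  if (iterations < 0) stop("iterations must be >= 0")
  structure(list(iterations = as.integer(iterations), w_length = w_length,
                 w_angle = w_angle, optimizer = "adam",
                 learning_rate = learning_rate, lr_final = lr_final,
                 solver_step = solver_step, rtol = rtol, atol = atol),
            class = "training_config")
}

# Evaluate code with a temporary RNG state seeded from `seed`.
with_seed <- function(seed, code) {
  had <- exists(".Random.seed", globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, globalenv())
    else if (exists(".Random.seed", globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(seed)
  force(code)
}

#' Initialize an untrained network model
#'
#' Weights are drawn from the Glorot (Xavier) uniform distribution,
#' `U(+-sqrt(6/(fan_in+fan_out)))`, biases start at zero; deterministic for
#' a given spec seed.
#'
#' @param spec a `network_spec`.
#' @param drivers optional `driver_set` the model will be simulated with.
#' @return object of class `ude_model` with empty loss history.
#' @export
init_network <- function(spec, drivers = NULL) {
  stopifnot(inherits(spec, "network_spec"))
  w <- spec$widths
  params <- with_seed(spec$seed, {
    W <- list(); b <- list()
    for (l in seq_len(length(w) - 1L)) {
      lim <- sqrt(6 / (w[l] + w[l + 1]))
      W[[l]] <- matrix(runif(w[l] * w[l + 1], -lim, lim), w[l + 1], w[l])
      b[[l]] <- rep(0, w[l + 1])
    }
    list(W = W, b = b)
  })
  structure(list(spec = spec, params = params, drivers = drivers,
                 config = NULL, loss_history = numeric(0),
                 x0 = rep(0, length(STATE_VARS))),
            class = "ude_model")
}

#' Number of trainable parameters
#' @param model a `ude_model`.
#' @return integer parameter count.
#' @export
n_parameters <- function(model) {
  sum(vapply(model$params$W, length, 1L)) + sum(vapply(model$params$b, length, 1L))
}

#' Evaluate the network right-hand side
#'
#' @param params parameter list (`W`, `b`) of a `ude_model`.
#' @param inputs numeric 8-vector `(states, drivers)` or an n x 8 matrix.
#' @param output_scale fixed multiplier on the output (see [network_spec()]).
#' @return 5-vector or n x 5 matrix of time derivatives.
#' @export
mlp_eval <- function(params, inputs, output_scale = 1) {
  vec_in <- is.null(dim(inputs))
  U <- if (vec_in) rbind(inputs) else as.matrix(inputs)
  out <- cpp_mlp_eval(params$W, params$b, U, output_scale)
  colnames(out) <- STATE_VARS
  if (vec_in) out[1, ] else out
}

#' Simulate the learned ODE
#'
#' Solves `dx/dt = ANN(x, drivers(t))` with an adaptive solver (lsoda) and
#' returns the state at the requested days.
#'
#' @param model a `ude_model`.
#' @param x0 initial 5-vector at `t_grid[1]`.
#' @param t_grid increasing days within the driver domain.
#' @param drivers a `driver_set`; defaults to the model's stored drivers.
#' @param rtol,atol solver tolerances (default from the model's config).
#' @return length(t_grid) x 5 matrix of states.
#' @export
simulate_ude <- function(model, x0, t_grid, drivers = model$drivers,
                         rtol = NULL, atol = NULL) {
  stopifnot(inherits(model, "ude_model"), !is.null(drivers))
  if (is.unsorted(t_grid, strictly = TRUE)) stop("t_grid must be strictly increasing")
  dom <- drivers[[1]]$domain
  if (t_grid[1] < dom[1] || t_grid[length(t_grid)] > dom[2])
    stop("t_grid outside driver domain")
  if (is.null(rtol)) rtol <- if (!is.null(model$config)) model$config$rtol else 1e-6
  if (is.null(atol)) atol <- if (!is.null(model$config)) model$config$atol else 1e-6
  params <- model$params
  scale <- model$spec$output_scale
  rhs <- function(t, y, parms) {
    d <- evaluate_drivers(drivers, min(max(t, dom[1]), dom[2]))
    list(as.numeric(mlp_eval(params, c(y, d), scale)))
  }
  times <- if (length(t_grid) == 1L) c(t_grid, t_grid) else t_grid
  sol <- deSolve::ode(y = as.numeric(x0), times = times, func = rhs,
                      parms = NULL, method = "lsoda", rtol = rtol, atol = atol)
  out <- unname(sol[seq_along(t_grid), -1, drop = FALSE])
  if (any(!is.finite(out)) || max(abs(out)) > 1e6)
    stop("ude simulation blew up (|x| > 1e6)")
  colnames(out) <- STATE_VARS
  out
}

#' Trajectory loss: length and angle differences
#'
#' `w_length * mean((|m_i| - |x_i|)^2) + w_angle * mean(1 - cos(m_i, x_i))`
#' over paired simulated/observed state vectors. Pairs where either vector
#' is zero contribute 0 to the angle term.
#'
#' @param simulated,observed matrices (rows = paired points) or vectors.
#' @param w_length,w_angle nonnegative weights (defaults 0.2 / 0.8).
#' @return nonnegative scalar.
#' @export
lda_loss <- function(simulated, observed, w_length = 0.2, w_angle = 0.8) {
  m <- if (is.null(dim(simulated))) rbind(simulated) else as.matrix(simulated)
  x <- if (is.null(dim(observed))) rbind(observed) else as.matrix(observed)
  if (!all(dim(m) == dim(x))) stop("simulated and observed shapes differ")
  lm_ <- sqrt(rowSums(m^2)); lx <- sqrt(rowSums(x^2))
  len <- mean((lm_ - lx)^2)
  nz <- lm_ > 1e-12 & lx > 1e-12
  ang <- ifelse(nz, 1 - rowSums(m * x) / (lm_ * lx), 0)
  w_length * len + w_angle * mean(ang)
}

# Build the training grid, driver matrices and observation bracketing used
# by the compiled kernel.
build_training_setup <- function(series, drivers, config) {
  t_nodes <- seq(1, 366, by = config$solver_step)
  if (t_nodes[length(t_nodes)] < 366) t_nodes <- c(t_nodes, 366)
  h <- diff(t_nodes)
  Dnode <- evaluate_drivers(drivers, t_nodes)
  Dmid <- evaluate_drivers(drivers, (t_nodes[-length(t_nodes)] + t_nodes[-1]) / 2)
  day <- series$day_of_year
  i <- findInterval(day, t_nodes)
  i[i >= length(t_nodes)] <- length(t_nodes) - 1L
  w <- (day - t_nodes[i]) / h[i]
  obs <- as.matrix(series[, STATE_VARS])
  list(t_nodes = t_nodes, h = h, Dnode = Dnode, Dmid = Dmid,
       obs_i = as.integer(i - 1L), obs_w = w, obs = unname(obs))
}

# Initial-state rule: mean of standardized observations in the first 30 days
# of the year; falls back to the overall mean if none exist.
initial_state <- function(series) {
  early <- series[series$day_of_year <= 30, STATE_VARS, drop = FALSE]
  if (nrow(early) == 0L) early <- series[, STATE_VARS, drop = FALSE]
  as.numeric(colMeans(early))
}

#' Train a network ODE against pooled observations
#'
#' Full-batch Adam on the trajectory loss between the simulated day-of-year
#' trajectory (linearly interpolated to each observation's day) and the
#' pooled standardized observations. If a step produces a non-finite loss or
#' the integration blows up, the step is rejected and the learning rate is
#' halved (logged via `message`).
#'
#' @param series standardized series (training split, complete records).
#' @param drivers a `driver_set`.
#' @param spec a `network_spec`.
#' @param config a `training_config`.
#' @return a trained `ude_model` with `loss_history` of length
#'   `config$iterations`.
#' @export
train_ude <- function(series, drivers, spec, config) {
  stopifnot(nrow(series) > 0)
  model <- init_network(spec, drivers)
  model$config <- config
  model$x0 <- initial_state(series)
  if (config$iterations == 0L) return(model)
  setup <- build_training_setup(series, drivers, config)

  shapes_W <- lapply(model$params$W, dim)
  len_W <- vapply(model$params$W, length, 1L)
  len_b <- vapply(model$params$b, length, 1L)
  n_state <- length(model$x0)
  # the initial state at day 1 is trained jointly with the weights (it is
  # only initialized from the early-year observation mean)
  theta <- c(unlist(model$params$W), unlist(model$params$b), model$x0)
  unflatten <- function(theta) {
    W <- list(); b <- list(); off <- 0L
    for (l in seq_along(len_W)) {
      W[[l]] <- matrix(theta[off + seq_len(len_W[l])], shapes_W[[l]][1], shapes_W[[l]][2])
      off <- off + len_W[l]
    }
    for (l in seq_along(len_b)) {
      b[[l]] <- theta[off + seq_len(len_b[l])]
      off <- off + len_b[l]
    }
    list(W = W, b = b, x0 = theta[off + seq_len(n_state)])
  }

  lr0 <- config$learning_rate
  lr_final <- if (is.null(config$lr_final)) lr0 else config$lr_final
  n_it <- config$iterations
  lr_cut <- 1   # halved on rejected steps
  b1 <- 0.9; b2 <- 0.999; adam_eps <- 1e-8
  mt <- vt <- numeric(length(theta))
  history <- numeric(config$iterations)
  last_loss <- Inf
  for (it in seq_len(config$iterations)) {
    lr <- if (n_it > 1) {
      (lr_final + 0.5 * (lr0 - lr_final) * (1 + cos(pi * (it - 1) / (n_it - 1)))) / lr_cut
    } else lr0 / lr_cut
    p <- unflatten(theta)
    res <- cpp_ude_loss_grad(p$W, p$b, p$x0, setup$h,
                             setup$Dnode, setup$Dmid,
                             setup$obs_i, setup$obs_w, setup$obs,
                             config$w_length, config$w_angle, TRUE,
                             spec$output_scale)
    if (!isTRUE(res$ok) || !is.finite(res$loss)) {
      lr_cut <- lr_cut * 2
      message(sprintf("train_ude: step %d rejected (unstable simulation), lr -> %g", it, lr / 2))
      history[it] <- last_loss
      next
    }
    g <- c(unlist(res$gradW), unlist(res$gradb), as.numeric(res$grad_x0))
    if (any(!is.finite(g))) stop("non-finite gradient at iteration ", it)
    history[it] <- last_loss <- res$loss
    mt <- b1 * mt + (1 - b1) * g
    vt <- b2 * vt + (1 - b2) * g^2
    mhat <- mt / (1 - b1^it)
    vhat <- vt / (1 - b2^it)
    theta <- theta - lr * mhat / (sqrt(vhat) + adam_eps)
  }
  if (!is.finite(history[1])) history[!is.finite(history)] <- NA_real_
  p <- unflatten(theta)
  model$params <- list(W = p$W, b = p$b)
  model$x0 <- p$x0
  model$loss_history <- history
  model$train_grid <- setup$t_nodes
  model
}

#' Train an ensemble of network ODE models
#'
#' Members differ only in their weight-initialization seed (derived
#' deterministically from the master seed). The ensemble is summarised by
#' the pointwise mean trajectory on a dense day grid.
#'
#' @param series,drivers,spec,config as in [train_ude()].
#' @param n_members number of members (reference value 20).
#' @param t_grid day grid for member/mean trajectories (default daily).
#' @param member_seeds optional explicit per-member seeds overriding the
#'   derivation from `spec$seed`.
#' @return object of class `ude_ensemble`: `members`, `t_grid`,
#'   `member_traj`, `mean_traj`, `member_mse` (each member's MSE to the
#'   ensemble mean).
#' @export
train_ensemble <- function(series, drivers, spec, config, n_members = 20,
                           t_grid = 1:366, member_seeds = NULL) {
  stopifnot(n_members >= 1)
  if (is.null(member_seeds))
    member_seeds <- with_seed(spec$seed, sample.int(2^30, n_members))
  members <- vector("list", n_members)
  for (k in seq_len(n_members)) {
    spec_k <- spec
    spec_k$seed <- as.integer(member_seeds[k])
    members[[k]] <- tryCatch(train_ude(series, drivers, spec_k, config),
                             error = function(e) {
                               warning("ensemble member ", k, " failed: ",
                                       conditionMessage(e))
                               NULL
                             })
  }
  ok <- !vapply(members, is.null, logical(1))
  if (sum(ok) < n_members / 2) stop("more than half the ensemble members failed")
  members <- members[ok]
  member_traj <- lapply(members, function(m)
    tryCatch(simulate_ude(m, m$x0, t_grid, drivers),
             error = function(e) {
               warning("dropping member with unstable trajectory: ",
                       conditionMessage(e))
               NULL
             }))
  ok2 <- !vapply(member_traj, is.null, logical(1))
  if (sum(ok2) < n_members / 2) stop("more than half the ensemble members failed")
  members <- members[ok2]
  member_traj <- member_traj[ok2]
  mean_traj <- Reduce(`+`, member_traj) / length(member_traj)
  member_mse <- vapply(member_traj, function(tr) mean((tr - mean_traj)^2), numeric(1))
  structure(list(members = members, t_grid = t_grid,
                 member_traj = member_traj, mean_traj = mean_traj,
                 member_mse = member_mse, seeds = member_seeds[ok][ok2]),
            class = "ude_ensemble")
}

#' Select the representative ensemble member
#'
#' The member whose trajectory has the smallest mean squared difference to
#' the ensemble mean; ties break to the lowest member index.
#'
#' @param ensemble a `ude_ensemble`.
#' @return the selected `ude_model` (index as attribute `index`).
#' @export
select_representative <- function(ensemble) {
  stopifnot(inherits(ensemble, "ude_ensemble"), length(ensemble$members) >= 1)
  idx <- which.min(ensemble$member_mse)
  out <- ensemble$members[[idx]]
  attr(out, "index") <- idx
  out
}
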