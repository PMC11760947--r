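# Sparse identification of nonlinear dynamics (SInDy).
#
# A second-order polynomial library over the 5 state variables and 3 drivers
# (45 functions: constant, 8 linear, 8 squares, 28 cross products) is fitted
# to (state, derivative) pairs harvested from the trained network by
# L1-penalized regression followed by an unpenalized least-squares refit on
# the selected support (the usual SInDy debiasing step).

# Coefficients with magnitude below this are snapped to exact zero so that
# "active basis function" counts are well-defined.
ZERO_SNAP <- 1e-8

#' Build the polynomial basis-function library
#'
#' Deterministic ordering: constant, linear terms in declaration order,
#' squares, then cross products in lexicographic pair order. With 5 states
#' and 3 drivers at order 2 this yields the 45-function library.
#'
#' @param state_vars,driver_vars character vectors of input names; defaults
#'   are the package's five states and three drivers.
#' @param order polynomial order, 1 or 2.
#' @return object of class `basis_library`: `vars`, `order`, `terms` (list of
#'   integer exponent vectors) and `names`.
#' @export
#' @examples
#' length(build_library()$names)  # 45
build_library <- function(state_vars = STATE_VARS, driver_vars = DRIVER_VARS,
                          order = 2) {
  if (!order %in% c(1L, 2L)) stop("unsupported library order: ", order)
  vars <- c(state_vars, driver_vars)
  n <- length(vars)
  terms <- list(integer(n))                       # constant
  for (i in seq_len(n)) {                         # linear
    e <- integer(n); e[i] <- 1L; terms <- c(terms, list(e))
  }
  if (order == 2L) {
    for (i in seq_len(n)) {                       # squares
      e <- integer(n); e[i] <- 2L; terms <- c(terms, list(e))
    }
    if (n >= 2L) for (i in seq_len(n - 1L)) for (j in (i + 1L):n) {
      e <- integer(n); e[i] <- 1L; e[j] <- 1L; terms <- c(terms, list(e))
    }
  }
  nm <- vapply(terms, function(e) {
    if (all(e == 0L)) return("1")
    parts <- character(0)
    for (k in seq_len(n)) {
      if (e[k] == 1L) parts <- c(parts, vars[k])
      if (e[k] == 2L) parts <- c(parts, paste0(vars[k], "^2"))
    }
    paste(parts, collapse = "*")
  }, character(1))
  structure(list(vars = vars, order = as.integer(order),
                 terms = terms, names = nm),
            class = "basis_library")
}

#' Evaluate the library on states and drivers
#'
#' @param library a `basis_library`.
#' @param state numeric 5-vector or matrix (rows = samples).
#' @param drivers numeric 3-vector or matrix matching `state`.
#' @return for vector input a named vector of length 45; for matrix input a
#'   samples x 45 matrix (the SInDy design matrix Theta).
#' @export
evaluate_library <- function(library, state, drivers) {
  stopifnot(inherits(library, "basis_library"))
  vec_in <- is.null(dim(state))
  X <- cbind(if (vec_in) rbind(state) else as.matrix(state),
             if (is.null(dim(drivers))) rbind(drivers) else as.matrix(drivers))
  if (ncol(X) != length(library$vars)) stop("input width does not match library variables")
  if (any(!is.finite(X))) stop("non-finite library inputs")
  Theta <- vapply(library$terms, function(e) {
    out <- rep(1, nrow(X))
    for (k in which(e > 0L)) out <- out * X[, k]^e[k]
    out
  }, numeric(nrow(X)))
  Theta <- matrix(Theta, nrow = nrow(X), dimnames = list(NULL, library$names))
  if (vec_in) Theta[1, ] else Theta
}

#' Harvest (state, derivative) pairs from a trained network model
#'
#' Simulates the model's own trajectory on the day grid and evaluates the
#' network right-hand side directly at the visited states (no finite
#' differencing), giving the derivative samples the sparse regression is
#' trained on. Because all 45 library features are smooth functions of the
#' day along a single annual trajectory, the regression design is severely
#' collinear there; a small Gaussian jitter of the query states (the
#' right-hand side is a state-space function, so off-trajectory queries are
#' well-defined) restores identifiability of the sparse support. Set
#' `jitter_sd = 0` for strictly on-trajectory samples.
#'
#' @param model a trained `ude_model`.
#' @param drivers a `driver_set`.
#' @param t_grid day grid, default daily 1..365.
#' @param x0 initial state; default the model's stored training x0.
#' @param jitter_sd standard deviation (z-units) of the state jitter.
#' @param seed seed for the jitter draw.
#' @return object of class `derivative_sample`: `t`, `X` (n x 5), `D`
#'   (n x 3), `Xdot` (n x 5).
#' @export
sample_derivatives <- function(model, drivers, t_grid = 1:365, x0 = NULL,
                               jitter_sd = 0.25, seed = 1) {
  stopifnot(inherits(model, "ude_model"))
  if (is.null(x0)) x0 <- model$x0
  X <- simulate_ude(model, x0, t_grid, drivers)
  if (jitter_sd > 0)
    X <- X + with_seed(seed, matrix(rnorm(length(X), 0, jitter_sd), nrow(X)))
  D <- evaluate_drivers(drivers, t_grid)
  Xdot <- mlp_eval(model$params, cbind(X, D), model$spec$output_scale)
  structure(list(t = t_grid, X = X, D = D, Xdot = Xdot),
            class = "derivative_sample")
}

#' Construct a derivative sample from explicit matrices
#'
#' Used for oracle tests and for analytic derivatives of a known system.
#' @param t day grid; `X`, `D`, `Xdot` matrices with matching rows.
#' @return a `derivative_sample`.
#' @export
derivative_sample <- function(t, X, D, Xdot) {
  X <- as.matrix(X); D <- as.matrix(D); Xdot <- as.matrix(Xdot)
  stopifnot(nrow(X) == length(t), nrow(D) == length(t), nrow(Xdot) == length(t))
  if (any(!is.finite(X)) || any(!is.finite(D)) || any(!is.finite(Xdot)))
    stop("non-finite entries in derivative sample")
  structure(list(t = t, X = X, D = D, Xdot = Xdot), class = "derivative_sample")
}

#' Fit sparse governing equations
#'
#' Per state equation: LASSO regression of the derivative on the library
#' features (no intercept beyond the library's constant column, no internal
#' standardization so the penalty acts on the interpretable coefficient
#' scale), followed by an unpenalized least-squares refit on the selected
#' support. Coefficients below 1e-8 are snapped to exact zero.
#'
#' @param sample a `derivative_sample`.
#' @param library a `basis_library`.
#' @param penalty LASSO penalty lambda (glmnet scale,
#'   `1/(2n) RSS + lambda * L1`); `0` gives the ordinary least-squares fit.
#' @return object of class `sparse_model`: `coef` (5 x 45 matrix, rows named
#'   by state variable, columns by basis function), `penalty`, `rss`
#'   (per-equation residual sum of squares of the refit), `n_active`.
#' @export
fit_sparse <- function(sample, library, penalty) {
  stopifnot(inherits(sample, "derivative_sample"), inherits(library, "basis_library"))
  Theta <- evaluate_library(library, sample$X, sample$D)
  n <- nrow(Theta); p <- ncol(Theta)
  if (n < p) warning("fewer derivative samples (", n, ") than basis functions (", p, ")")
  n_eq <- ncol(sample$Xdot)
  coefs <- matrix(0, n_eq, p, dimnames = list(colnames(sample$Xdot), library$names))
  rss <- numeric(n_eq); n_active <- integer(n_eq)
  for (i in seq_len(n_eq)) {
    y <- sample$Xdot[, i]
    if (all(abs(y) < ZERO_SNAP)) { rss[i] <- 0; next }
    if (penalty > 0) {
      fit <- glmnet::glmnet(Theta, y, alpha = 1, lambda = penalty,
                            intercept = FALSE, standardize = FALSE,
                            thresh = 1e-12, maxit = 1e6)
      beta <- as.numeric(fit$beta)
      support <- which(abs(beta) > ZERO_SNAP)
    } else {
      support <- seq_len(p)
    }
    if (length(support) > 0) {
      cf <- refit_support(Theta, y, support)
      cf[abs(cf) < ZERO_SNAP] <- 0
      coefs[i, support] <- cf
    }
    resid <- y - Theta %*% coefs[i, ]
    rss[i] <- sum(resid^2)
    n_active[i] <- sum(coefs[i, ] != 0)
  }
  structure(list(coef = coefs, penalty = penalty, rss = rss,
                 n_active = n_active, library = library),
            class = "sparse_model")
}

# Unpenalized least-squares refit on a support; aliased columns are dropped
# (coefficient 0) with a message.
refit_support <- function(Theta, y, support) {
  Xs <- Theta[, support, drop = FALSE]
  qr_fit <- qr(Xs)
  if (qr_fit$rank < ncol(Xs)) {
    keep <- qr_fit$pivot[seq_len(qr_fit$rank)]
    message("fit_sparse: dropping ", ncol(Xs) - qr_fit$rank,
            " aliased column(s) from refit")
    cf <- rep(0, ncol(Xs))
    cf[keep] <- qr.coef(qr(Xs[, keep, drop = FALSE]), y)
    cf
  } else {
    as.numeric(qr.coef(qr_fit, y))
  }
}

#' Tune the sparsity penalty
#'
#' Scans a penalty grid and selects the value minimizing
#' `sum(RSS) + kappa * sum(active terms)`, trading accuracy against sparsity.
#' Ties go to the smallest penalty. `kappa` is in units of residual sum of
#' squares per retained term; the default was calibrated once on the
#' two-bloom synthetic preset so that the known support is recovered.
#'
#' @param sample a `derivative_sample`.
#' @param library a `basis_library`.
#' @param penalty_grid numeric vector of candidate penalties.
#' @param kappa sparsity weight.
#' @return the selected penalty (with the scan as attribute `scan`).
#' @export
tune_sparsity <- function(sample, library, penalty_grid, kappa = 5e-4) {
  stopifnot(length(penalty_grid) >= 1)
  grid <- sort(penalty_grid)
  score <- vapply(grid, function(lam) {
    fit <- fit_sparse(sample, library, lam)
    sum(fit$rss) + kappa * sum(fit$n_active)
  }, numeric(1))
  best <- grid[which.min(score)]
  attr(best, "scan") <- data.frame(penalty = grid, score = score)
  best
}

#' Render a sparse model as readable differential equations
#'
#' One line per state variable, `d<var>/dt = c1*f1 + c2*f2 + ...`, listing
#' only active terms with 6 significant digits. [parse_equations()] restores
#' the coefficient matrix from this text.
#'
#' @param model a `sparse_model`.
#' @return character vector of equation lines.
#' @export
to_equations <- function(model) {
  stopifnot(inherits(model, "sparse_model"))
  vars <- rownames(model$coef)
  terms <- colnames(model$coef)
  vapply(seq_along(vars), function(i) {
    act <- which(model$coef[i, ] != 0)
    if (length(act) == 0) return(paste0("d", vars[i], "/dt = 0"))
    rhs <- vapply(act, function(j) {
      cf <- sprintf("%.6g", model$coef[i, j])
      if (terms[j] == "1") cf else paste0(cf, "*", terms[j])
    }, character(1))
    paste0("d", vars[i], "/dt = ", paste(rhs, collapse = " + "))
  }, character(1))
}

#' @rdname to_equations
#' @param lines character vector produced by [to_equations()].
#' @param library the `basis_library` defining term names and ordering.
#' @return a 5 x 45 coefficient matrix.
#' @export
parse_equations <- function(lines, library) {
  stopifnot(inherits(library, "basis_library"))
  n_eq <- length(lines)
  vars <- sub("^d(.+)/dt = .*$", "\\1", lines)
  coefs <- matrix(0, n_eq, length(library$names),
                  dimnames = list(vars, library$names))
  for (i in seq_len(n_eq)) {
    rhs <- sub("^d.+/dt = ", "", lines[i])
    if (rhs == "0") next
    for (piece in strsplit(rhs, " + ", fixed = TRUE)[[1]]) {
      parts <- strsplit(piece, "*", fixed = TRUE)[[1]]
      cf <- as.numeric(parts[1])
      term <- if (length(parts) == 1L) "1" else paste(parts[-1], collapse = "*")
      j <- match(term, library$names)
      if (is.na(j)) stop("unknown basis function in equation text: ", term)
      coefs[i, j] <- cf
    }
  }
  coefs
}

#' Export a sparse model as a long-format CSV
#'
#' @param model a `sparse_model`.
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_sparse_model <- function(model, path) {
  act <- which(model$coef != 0, arr.ind = TRUE)
  df <- data.frame(
    equation = rownames(model$coef)[act[, 1]],
    term = colnames(model$coef)[act[, 2]],
    coefficient = model$coef[act]
  )
  df <- df[order(match(df$equation, rownames(model$coef))), ]
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}
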