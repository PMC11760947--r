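# Seasonal baseline and fit metrics.
#
# A penalized cyclic cubic regression spline over day-of-year serves as the
# descriptive baseline curve the dynamical models are compared against. The
# full mixed-model treatment (station/year random effects, REML) is
# deliberately omitted: the baseline's only job here is to provide the
# comparison curve, and pooling stations and years matches how the dynamic
# models are trained. This is a documented simplification.

#' Fit a cyclic seasonal smoother
#'
#' Penalized regression with a cyclic cubic spline basis over day-of-year,
#' boundary knots at days 1 and 366 so the curve closes the annual cycle
#' exactly. The smoothing parameter is chosen by generalized
#' cross-validation unless supplied.
#'
#' @param t_obs day-of-year values.
#' @param y_obs observed (standardized) values.
#' @param n_knots spline basis dimension (default 12, roughly monthly).
#' @param smoothing optional fixed smoothing parameter (`sp` of the smooth).
#' @param variable label stored with the model.
#' @return object of class `smoother_model` wrapping the `mgcv::gam` fit.
#' @export
fit_cyclic_smoother <- function(t_obs, y_obs, n_knots = 12, smoothing = NULL,
                                variable = "chla") {
  stopifnot(length(t_obs) == length(y_obs))
  if (length(unique(t_obs)) < n_knots)
    stop("need at least n_knots distinct day-of-year values")
  df <- data.frame(doy = t_obs, y = y_obs)
  knots <- list(doy = seq(1, 366, length.out = n_knots))
  fit <- if (is.null(smoothing)) {
    mgcv::gam(y ~ s(doy, bs = "cc", k = n_knots), data = df, knots = knots,
              method = "GCV.Cp")
  } else {
    mgcv::gam(y ~ s(doy, bs = "cc", k = n_knots), data = df, knots = knots,
              sp = smoothing)
  }
  structure(list(variable = variable, fit = fit, n_knots = n_knots,
                 domain = c(1, 366)),
            class = "smoother_model")
}

#' Predict from a cyclic smoother
#'
#' @param model a `smoother_model`.
#' @param t_grid days within \[1, 366\].
#' @param se if `TRUE`, also return pointwise standard errors.
#' @return numeric vector of predictions (or a data frame with `fit`, `se`).
#' @export
predict_smoother <- function(model, t_grid, se = FALSE) {
  stopifnot(inherits(model, "smoother_model"))
  if (any(t_grid < model$domain[1] | t_grid > model$domain[2]))
    stop("prediction day outside [1, 366]")
  nd <- data.frame(doy = t_grid)
  if (se) {
    p <- predict(model$fit, newdata = nd, se.fit = TRUE)
    data.frame(day = t_grid, fit = as.numeric(p$fit), se = as.numeric(p$se.fit))
  } else {
    as.numeric(predict(model$fit, newdata = nd))
  }
}

#' Mean squared error between observations and a model curve
#'
#' `(1/N) * sum((m_i - x_i)^2)` over the N observations, with the model
#' curve linearly interpolated from its dense grid to each observation day.
#'
#' @param obs data frame with columns `day` and `value` (N >= 1 rows).
#' @param pred data frame with columns `day` and `value` (dense grid), or a
#'   numeric vector aligned with `obs$day`.
#' @return nonnegative scalar.
#' @export
mse_data_model <- function(obs, pred) {
  if (nrow(obs) == 0) stop("no observations")
  m <- if (is.numeric(pred)) {
    if (length(pred) != nrow(obs)) stop("prediction length mismatch")
    pred
  } else {
    stats::approx(pred$day, pred$value, xout = obs$day, rule = 2)$y
  }
  mean((m - obs$value)^2)
}

#' Mean squared error between two model curves
#'
#' `(1/N) * sum((m_i^A - m_i^B)^2)` on a shared day grid; symmetric.
#'
#' @param pred_a,pred_b data frames with columns `day` and `value` on the
#'   same grid, or aligned numeric vectors.
#' @return nonnegative scalar.
#' @export
mse_model_model <- function(pred_a, pred_b) {
  a <- if (is.numeric(pred_a)) pred_a else pred_a$value
  b <- if (is.numeric(pred_b)) pred_b else pred_b$value
  if (!is.numeric(pred_a) && !is.numeric(pred_b) &&
      (nrow(pred_a) != nrow(pred_b) || any(pred_a$day != pred_b$day)))
    stop("prediction grids differ")
  if (length(a) != length(b)) stop("prediction grids differ")
  mean((a - b)^2)
}
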