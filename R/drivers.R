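# Seasonal forcing: Temp(t), Sal(t), Kd(t) as polynomials in day-of-year.
#
# Fits are ordinary least squares on the standardized training observations,
# pooled over stations and years of one blooming pattern. Time is rescaled to
# tau = t/366 before building the monomial design so that high-order fits stay
# well conditioned; coefficients are stored in the tau scale.

YEAR_SCALE <- 366
DRIVER_DOMAIN <- c(1, 366)

#' Fit a polynomial seasonal driver
#'
#' Ordinary least-squares polynomial of the given order in rescaled
#' day-of-year `tau = t/366`. The defaults of the pipeline are order 5 for
#' temperature and order 4 for salinity and Kd.
#'
#' @param t_obs day-of-year values (1..366).
#' @param y_obs z-scored driver observations.
#' @param order polynomial order (degree).
#' @param variable driver name, one of `"temp"`, `"sal"`, `"kd"` (or any
#'   label for synthetic use).
#' @return object of class `driver_model`: `variable`, `order`, `coef`
#'   (length order+1, ascending degree, tau scale), `domain`, `rss`, `n`.
#' @export
fit_driver_polynomial <- function(t_obs, y_obs, order, variable = "driver") {
  stopifnot(length(t_obs) == length(y_obs), order >= 0)
  if (length(unique(t_obs)) < order + 1)
    stop("need at least order+1 distinct day-of-year values")
  tau <- t_obs / YEAR_SCALE
  X <- outer(tau, 0:order, `^`)
  fit <- lm.fit(X, y_obs)
  if (fit$rank < order + 1) stop("rank-deficient polynomial design")
  cf <- unname(fit$coefficients)
  structure(list(variable = variable, order = as.integer(order), coef = cf,
                 domain = DRIVER_DOMAIN, rss = sum(fit$residuals^2),
                 n = length(y_obs)),
            class = "driver_model")
}

# Horner evaluation of a driver_model at day-of-year t (vectorized).
eval_driver <- function(model, t) {
  tau <- t / YEAR_SCALE
  y <- rep(0, length(tau))
  for (c_k in rev(model$coef)) y <- y * tau + c_k
  y
}

#' Fit the three seasonal drivers from standardized series
#'
#' @param series standardized series data frame (training split) from
#'   [log_zscore()].
#' @param orders named integer vector of polynomial orders.
#' @return object of class `driver_set`: named list of three `driver_model`s.
#' @export
fit_drivers <- function(series, orders = c(temp = 5, sal = 4, kd = 4)) {
  models <- lapply(names(orders), function(v)
    fit_driver_polynomial(series$day_of_year, series[[v]], orders[[v]], variable = v))
  names(models) <- names(orders)
  structure(models, class = "driver_set")
}

#' Construct a driver set from explicit coefficients
#'
#' Used by the synthetic-data generator, where the polynomials themselves are
#' the ground truth.
#'
#' @param coefs named list of numeric coefficient vectors (ascending degree,
#'   tau = t/366 scale) for `temp`, `sal`, `kd`.
#' @return a `driver_set`.
#' @export
driver_set_from_coef <- function(coefs) {
  stopifnot(all(c("temp", "sal", "kd") %in% names(coefs)))
  models <- lapply(names(coefs), function(v)
    structure(list(variable = v, order = length(coefs[[v]]) - 1L,
                   coef = as.numeric(coefs[[v]]), domain = DRIVER_DOMAIN,
                   rss = NA_real_, n = NA_integer_),
              class = "driver_model"))
  names(models) <- names(coefs)
  structure(models, class = "driver_set")
}

#' Evaluate the three drivers at given days
#'
#' @param drivers a `driver_set`.
#' @param t day-of-year value(s) within the fit domain \[1, 366\]; no
#'   extrapolation is allowed.
#' @return for scalar `t` a named 3-vector (temp, sal, kd); for vector `t` a
#'   length(t) x 3 matrix.
#' @export
evaluate_drivers <- function(drivers, t) {
  stopifnot(inherits(drivers, "driver_set"))
  dom <- drivers[[1]]$domain
  if (any(t < dom[1] | t > dom[2]))
    stop("day-of-year outside driver domain [", dom[1], ", ", dom[2], "]")
  out <- vapply(drivers, eval_driver, numeric(length(t)), t = t)
  if (length(t) == 1L) {
    out <- stats::setNames(as.numeric(out), names(drivers))
  } else {
    out <- matrix(out, nrow = length(t), dimnames = list(NULL, names(drivers)))
  }
  out
}

#' Serialize a driver set to JSON (and back)
#'
#' @param drivers a `driver_set`.
#' @param path file path.
#' @return `path` invisibly / the restored `driver_set`.
#' @export
write_driver_set <- function(drivers, path) {
  stopifnot(inherits(drivers, "driver_set"))
  jsonlite::write_json(lapply(drivers, unclass), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_driver_set
#' @export
read_driver_set <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  models <- lapply(x, function(m)
    structure(list(variable = m$variable, order = as.integer(m$order),
                   coef = as.numeric(m$coef), domain = as.numeric(m$domain),
                   rss = if (is.null(m$rss)) NA_real_ else m$rss,
                   n = if (is.null(m$n)) NA_integer_ else m$n),
              class = "driver_model"))
  structure(models, class = "driver_set")
}
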