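#' phytodyn: governing equations for phytoplankton blooms from monitoring data
#'
#' See the methods vignette (`vignette("phytodyn-methods")`) for the model,
#' the training procedure and the design choices.
#'
#' @keywords internal
#' @useDynLib phytodyn, .registration = TRUE
#' @importFrom Rcpp evalCpp
#' @importFrom stats coef lm lm.fit lsfit pnorm dnorm rnorm runif sd predict
#' @importFrom utils read.csv write.csv head tail
"_PACKAGE"

# The five ODE state variables and the three external drivers, in the fixed
# order used throughout: library construction, network inputs, coefficient
# matrices and all exported tables rely on this ordering.
STATE_VARS  <- c("chla", "din", "dip", "totn", "totp")
DRIVER_VARS <- c("temp", "sal", "kd")
ALL_VARS    <- c(STATE_VARS, DRIVER_VARS)

# Additive shift applied to water temperature (degC) before the log
# transform, so sub-zero winter temperatures stay in the log's domain.
DEFAULT_TEMP_SHIFT <- 5

#' Convert Secchi depth to a light attenuation coefficient
#'
#' Uses the empirical conversion `Kd = 1.32 / Secchi`, which expresses light
#' attenuation (1/m) as inversely proportional to the depth at which a Secchi
#' disk disappears.
#'
#' @param secchi Secchi depth in metres; strictly positive.
#' @return Light attenuation coefficient Kd in 1/m.
#' @export
#' @examples
#' secchi_to_kd(1)    # 1.32
#' secchi_to_kd(2)    # 0.66
secchi_to_kd <- function(secchi) {
  if (!is.numeric(secchi)) stop("secchi depth must be numeric")
  bad <- is.finite(secchi) & secchi <= 0
  if (any(bad, na.rm = TRUE)) stop("secchi depth must be strictly positive")
  1.32 / secchi
}

#' Ordinal day of the year
#'
#' @param date a `Date` or something `as.Date()` can parse (ISO-8601).
#' @return integer day of year in 1..366 (366 only in leap years).
#' @export
to_day_of_year <- function(date) {
  d <- as.Date(date)
  if (any(is.na(d))) stop("unparseable date: ", paste(date[is.na(d)], collapse = ", "))
  as.integer(strftime(d, "%j"))
}

#' Drop records with missing state variables or drivers
#'
#' Keeps only records where all five state variables (Chl-a, DIN, DIP, totN,
#' totP), temperature and salinity are present and at least one of Secchi
#' depth / Kd is present (Kd is derivable from Secchi and vice versa).
#' Surviving records are returned unaltered; the number removed is attached
#' as attribute `n_removed` and reported via `message()`.
#'
#' @param records data frame of raw monitoring records (see
#'   [read_monitoring_csv()] for the column contract).
#' @return the complete records, with attribute `n_removed`.
#' @export
drop_incomplete <- function(records) {
  has <- function(col) {
    if (!col %in% names(records)) rep(FALSE, nrow(records)) else !is.na(records[[col]])
  }
  keep <- has("chla") & has("din") & has("dip") & has("totn") & has("totp") &
    has("temp") & has("sal") & (has("secchi") | has("kd"))
  out <- records[keep, , drop = FALSE]
  n_removed <- nrow(records) - nrow(out)
  if (nrow(out) == 0L) warning("no complete records remain")
  message(sprintf("drop_incomplete: removed %d of %d records", n_removed, nrow(records)))
  attr(out, "n_removed") <- n_removed
  out
}

#' Split records into training and validation years
#'
#' Partitions by calendar year. Records outside both ranges are returned in
#' the `excluded` element so the three pieces always form a partition of the
#' input.
#'
#' @param records data frame with a `date` column.
#' @param train_years,valid_years integer vectors of calendar years; must be
#'   disjoint. Defaults follow the 2000-2018 training / 2019-2021 validation
#'   split of the source monitoring campaign.
#' @return list with elements `train`, `validation`, `excluded`.
#' @export
split_by_year <- function(records, train_years = 2000:2018, valid_years = 2019:2021) {
  if (length(intersect(train_years, valid_years)) > 0L)
    stop("train_years and valid_years overlap")
  yr <- as.integer(strftime(as.Date(records$date), "%Y"))
  out <- list(
    train      = records[yr %in% train_years, , drop = FALSE],
    validation = records[yr %in% valid_years, , drop = FALSE],
    excluded   = records[!(yr %in% train_years) & !(yr %in% valid_years), , drop = FALSE]
  )
  if (nrow(out$excluded) > 0L)
    message(sprintf("split_by_year: %d records outside both year ranges excluded",
                    nrow(out$excluded)))
  out
}

#' Fit log/z-score standardization statistics
#'
#' Computes, for each of the eight variables (five states plus Temp, Sal,
#' Kd), the mean and sample standard deviation of the natural-log-transformed
#' values. Temperature is shifted by `temp_shift` degC before the log so
#' freezing-point values remain in the domain. Kd is taken from the `kd`
#' column where present, otherwise derived from Secchi depth.
#'
#' The statistics must be computed from training-split records of a single
#' blooming pattern (stations and years pooled); the same spec is then applied
#' to the validation records of that pattern.
#'
#' @param records complete raw records (see [drop_incomplete()]).
#' @param temp_shift additive shift (degC) applied to temperature before log.
#' @return an object of class `transform_spec`: named lists `mean` and `sd`
#'   plus the `temp_shift` used.
#' @export
fit_transform_spec <- function(records, temp_shift = DEFAULT_TEMP_SHIFT) {
  lv <- log_values(records, temp_shift)
  mu <- lapply(lv, mean)
  sdv <- lapply(lv, sd)
  for (v in ALL_VARS) {
    if (!is.finite(sdv[[v]]) || sdv[[v]] <= 0)
      stop("degenerate data: zero variance in variable '", v, "'")
  }
  structure(list(mean = mu, sd = sdv, temp_shift = temp_shift),
            class = "transform_spec")
}

# Natural-log values of the 8 variables as a named list of vectors.
log_values <- function(records, temp_shift) {
  kd <- if ("kd" %in% names(records)) records$kd else rep(NA_real_, nrow(records))
  if ("secchi" %in% names(records)) {
    use <- is.na(kd) & !is.na(records$secchi)
    kd[use] <- secchi_to_kd(records$secchi[use])
  }
  raw <- list(
    chla = records$chla, din = records$din, dip = records$dip,
    totn = records$totn, totp = records$totp,
    temp = records$temp + temp_shift, sal = records$sal, kd = kd
  )
  lapply(stats::setNames(ALL_VARS, ALL_VARS), function(v) {
    x <- raw[[v]]
    if (any(is.na(x))) stop("missing values in variable '", v, "'; run drop_incomplete() first")
    if (any(x <= 0)) stop("non-positive value in variable '", v, "' cannot be log-transformed")
    log(x)
  })
}

#' Standardize monitoring records to z-scored day-of-year series
#'
#' Applies natural log then (x - mean)/sd per variable using a previously
#' fitted [fit_transform_spec()]. The result is the pooled day-of-year data
#' set the ODE models are trained on.
#'
#' @param records complete raw records.
#' @param spec a `transform_spec`.
#' @return data frame with columns `pattern`, `station_id`, `year`,
#'   `day_of_year` and the eight z-scored variables
#'   (`chla`,`din`,`dip`,`totn`,`totp`,`temp`,`sal`,`kd`).
#' @export
log_zscore <- function(records, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  lv <- log_values(records, spec$temp_shift)
  z <- lapply(stats::setNames(ALL_VARS, ALL_VARS), function(v)
    (lv[[v]] - spec$mean[[v]]) / spec$sd[[v]])
  d <- as.Date(records$date)
  out <- data.frame(
    pattern = if ("pattern" %in% names(records)) records$pattern else NA_character_,
    station_id = records$station_id,
    year = as.integer(strftime(d, "%Y")),
    day_of_year = to_day_of_year(d),
    stringsAsFactors = FALSE
  )
  for (v in ALL_VARS) out[[v]] <- z[[v]]
  out
}

#' Invert the log/z-score transform
#'
#' Maps z-scores back to the raw measurement scale: `exp(z*sd + mean)`, with
#' the temperature shift removed. Exact inverse of [log_zscore()].
#'
#' @param z data frame or named list with (a subset of) the eight z-scored
#'   variables.
#' @param spec the `transform_spec` used for standardization.
#' @return the same structure with raw-scale values.
#' @export
invert_zscore <- function(z, spec) {
  stopifnot(inherits(spec, "transform_spec"))
  out <- z
  for (v in intersect(names(z), ALL_VARS)) {
    x <- exp(z[[v]] * spec$sd[[v]] + spec$mean[[v]])
    if (v == "temp") x <- x - spec$temp_shift
    out[[v]] <- x
  }
  out
}

#' Read a raw monitoring CSV
#'
#' Expected columns: `station_id`, `date` (ISO-8601), `chla`, `din`, `dip`,
#' `totn`, `totp`, `temp`, `sal`, `secchi` and/or `kd`, `pattern`. Missing
#' values are empty fields or NA.
#'
#' @param path file path.
#' @return data frame of raw records.
#' @export
read_monitoring_csv <- function(path) {
  rec <- read.csv(path, stringsAsFactors = FALSE)
  needed <- c("station_id", "date", STATE_VARS, "temp", "sal", "pattern")
  miss <- setdiff(needed, names(rec))
  if (length(miss)) stop("monitoring CSV lacks columns: ", paste(miss, collapse = ", "))
  if (!any(c("secchi", "kd") %in% names(rec)))
    stop("monitoring CSV needs a 'secchi' or 'kd' column")
  rec
}

#' Write standardized series / read them back
#'
#' @param series standardized series data frame from [log_zscore()].
#' @param path file path.
#' @return `path`, invisibly.
#' @export
write_standardized_csv <- function(series, path) {
  write.csv(series, path, row.names = FALSE)
  invisible(path)
}

#' Serialize a transform spec to JSON (and back)
#'
#' @param spec a `transform_spec`.
#' @param path file path.
#' @return `path` invisibly / the restored `transform_spec`.
#' @export
write_transform_spec <- function(spec, path) {
  stopifnot(inherits(spec, "transform_spec"))
  jsonlite::write_json(unclass(spec), path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_transform_spec
#' @export
read_transform_spec <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  structure(list(mean = as.list(x$mean), sd = as.list(x$sd),
                 temp_shift = x$temp_shift),
            class = "transform_spec")
}
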