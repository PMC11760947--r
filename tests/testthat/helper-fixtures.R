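# Small in-code fixtures shared across tests.

# A tiny complete raw-record table spanning both year ranges.
make_records <- function(n = 24, seed = 42, years = c(2005, 2012, 2019)) {
  withr_seed <- function(code) { set.seed(seed); code }
  withr_seed({
    dates <- as.Date(sprintf("%d-%02d-%02d",
                             rep(years, length.out = n),
                             sample(1:12, n, TRUE), sample(1:28, n, TRUE)))
    data.frame(
      station_id = sprintf("S%02d", sample(1:3, n, TRUE)),
      date = as.character(dates),
      chla = exp(rnorm(n, log(5), 0.5)),
      din = exp(rnorm(n, log(6), 0.5)),
      dip = exp(rnorm(n, log(0.5), 0.5)),
      totn = exp(rnorm(n, log(35), 0.3)),
      totp = exp(rnorm(n, log(1.2), 0.3)),
      temp = exp(rnorm(n, log(15), 0.3)) - 5,
      sal = exp(rnorm(n, log(10), 0.1)),
      secchi = exp(rnorm(n, log(1.5), 0.3)),
      pattern = "fixture",
      stringsAsFactors = FALSE
    )
  })
}

# Cached preset and its noiseless dataset/standardization (built once per run).
preset_cache <- new.env()
get_preset <- function() {
  if (is.null(preset_cache$sys))
    preset_cache$sys <- make_two_bloom_preset(seed = 1, noise_sd = 0,
                                              missing_rate = 0)
  preset_cache$sys
}
get_truth_traj <- function() {
  if (is.null(preset_cache$truth))
    preset_cache$truth <- simulate_truth(get_preset())
  preset_cache$truth
}

# Local maxima above zero of a series.
peak_days <- function(y, days = seq_along(y)) {
  i <- which(diff(sign(diff(y))) == -2) + 1
  days[i[y[i] > 0]]
}
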