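# End-to-end orchestration: configuration, seeding, and the staged pipeline
# (preprocess -> drivers -> baseline + ensemble -> sparse equations ->
# interpretation -> evaluation) with a reproducible artifact manifest.

default_config <- function() {
  list(
    input = NULL,                 # path to a monitoring CSV, or NULL
    preset = "two_bloom",         # synthetic preset when input is NULL
    pattern = NULL,               # pattern label to analyse (NULL = first)
    temp_shift = DEFAULT_TEMP_SHIFT,
    train_years = 2000:2018,
    valid_years = 2019:2021,
    driver_orders = c(temp = 5, sal = 4, kd = 4),
    hidden = c(16, 16, 16, 16),
    iterations = 500,
    n_members = 20,
    w_length = 0.2,
    w_angle = 0.8,
    learning_rate = 3e-2,
    lr_final = 3e-3,
    solver_step = 1,
    penalty_grid = 10^seq(-6, log10(3e-4), length.out = 10),
    kappa = 5e-4,
    jitter_sd = 0.25,
    n_knots = 12,
    min_window_days = 5,
    seed = 1,
    outdir = "phytodyn_out"
  )
}

#' Load and validate a pipeline configuration
#'
#' Reads a YAML (or JSON) file, rejects unknown keys, and fills defaults:
#' driver polynomial orders 5/4/4, four hidden layers of 16, 500 training
#' iterations, 20 ensemble members, loss weights 0.2/0.8.
#'
#' @param path config file path; `NULL` returns the defaults.
#' @return a validated `pipeline_config` list.
#' @export
load_config <- function(path = NULL) {
  cfg <- default_config()
  if (!is.null(path)) {
    user <- yaml::read_yaml(path)
    unknown <- setdiff(names(user), names(cfg))
    if (length(unknown))
      stop("unknown config key(s): ", paste(unknown, collapse = ", "))
    for (k in names(user)) cfg[[k]] <- user[[k]]
  }
  cfg$driver_orders <- unlist(cfg$driver_orders)
  if (!all(c("temp", "sal", "kd") %in% names(cfg$driver_orders)))
    stop("driver_orders must name temp, sal and kd")
  if (length(intersect(cfg$train_years, cfg$valid_years)))
    stop("train_years and valid_years overlap")
  cfg$seed <- as.integer(cfg$seed)
  structure(cfg, class = "pipeline_config")
}

#' Save a pipeline configuration
#' @param config a `pipeline_config`.
#' @param path output YAML path.
#' @return `path`, invisibly.
#' @export
save_config <- function(config, path) {
  cfg <- unclass(config)
  cfg$driver_orders <- as.list(cfg$driver_orders)  # keep names in YAML
  yaml::write_yaml(cfg, path)
  invisible(path)
}

#' Run the full analysis pipeline
#'
#' Stages: (1) obtain raw records (from `config$input` or the synthetic
#' preset), (2) drop incomplete records, split by year, fit the transform
#' spec on training years and standardize, (3) fit driver polynomials,
#' (4) fit the cyclic baseline and train the network-ODE ensemble, (5)
#' select the representative member, harvest derivatives, tune the sparsity
#' penalty and fit the sparse equations, (6) compute term contributions,
#' growth windows and rankings, (7) evaluate training/validation MSEs of
#' baseline and ensemble mean. All outputs are written under
#' `config$outdir` and listed, with MD5 digests, in `manifest.json`.
#'
#' @param config a `pipeline_config` (see [load_config()]).
#' @return the manifest, invisibly: a list with `seed`, `config_digest` and
#'   per-file digests.
#' @export
run_pipeline <- function(config = load_config()) {
  dir.create(config$outdir, showWarnings = FALSE, recursive = TRUE)
  out <- function(name) file.path(config$outdir, name)
  files <- character(0)
  emit <- function(name) files <<- c(files, out(name))

  # -- stage 1: records
  if (!is.null(config$input)) {
    records <- read_monitoring_csv(config$input)
  } else {
    system <- make_two_bloom_preset(seed = config$seed)
    ds <- generate_monitoring(system)
    records <- ds$records
    write_sparse_truth <- data.frame(
      equation = rownames(system$coef)[which(system$coef != 0, arr.ind = TRUE)[, 1]],
      term = colnames(system$coef)[which(system$coef != 0, arr.ind = TRUE)[, 2]],
      coefficient = system$coef[system$coef != 0])
    write.csv(write_sparse_truth, out("ground_truth.csv"), row.names = FALSE)
    emit("ground_truth.csv")
    write.csv(records, out("records.csv"), row.names = FALSE)
    emit("records.csv")
  }
  pattern <- if (is.null(config$pattern)) records$pattern[1] else config$pattern
  records <- records[records$pattern == pattern, , drop = FALSE]

  # -- stage 2: preprocessing
  records <- suppressMessages(drop_incomplete(records))
  split <- split_by_year(records, config$train_years, config$valid_years)
  tspec <- fit_transform_spec(split$train, temp_shift = config$temp_shift)
  train <- log_zscore(split$train, tspec)
  valid <- if (nrow(split$validation)) log_zscore(split$validation, tspec) else NULL
  write_transform_spec(tspec, out("transform_spec.json")); emit("transform_spec.json")
  write_standardized_csv(train, out("train_standardized.csv")); emit("train_standardized.csv")
  if (!is.null(valid)) {
    write_standardized_csv(valid, out("valid_standardized.csv"))
    emit("valid_standardized.csv")
  }

  # -- stage 3: drivers
  drivers <- fit_drivers(train, orders = config$driver_orders)
  write_driver_set(drivers, out("drivers.json")); emit("drivers.json")

  # -- stage 4: baseline + ensemble
  t_grid <- 1:366
  baseline <- fit_cyclic_smoother(train$day_of_year, train$chla,
                                  n_knots = config$n_knots)
  base_curve <- predict_smoother(baseline, t_grid, se = TRUE)
  write.csv(base_curve, out("baseline_chla.csv"), row.names = FALSE)
  emit("baseline_chla.csv")

  spec <- network_spec(hidden = config$hidden, seed = config$seed)
  tcfg <- training_config(iterations = config$iterations,
                          w_length = config$w_length, w_angle = config$w_angle,
                          learning_rate = config$learning_rate,
                          lr_final = config$lr_final,
                          solver_step = config$solver_step)
  ensemble <- train_ensemble(train, drivers, spec, tcfg,
                             n_members = config$n_members, t_grid = t_grid)
  mean_df <- data.frame(day = t_grid, ensemble$mean_traj)
  write.csv(mean_df, out("ensemble_mean.csv"), row.names = FALSE)
  emit("ensemble_mean.csv")

  # -- stage 5: sparse equations
  representative <- select_representative(ensemble)
  library <- build_library()
  sample <- sample_derivatives(representative, drivers,
                               jitter_sd = config$jitter_sd,
                               seed = config$seed)
  penalty <- tune_sparsity(sample, library, config$penalty_grid,
                           kappa = config$kappa)
  sparse <- fit_sparse(sample, library, as.numeric(penalty))
  writeLines(to_equations(sparse), out("equations.txt")); emit("equations.txt")
  write_sparse_model(sparse, out("sparse_model.csv")); emit("sparse_model.csv")

  # -- stage 6: interpretation
  terms <- term_timeseries(sparse, sample)
  write.csv(terms, out("term_contributions.csv"), row.names = FALSE)
  emit("term_contributions.csv")
  fitted <- attr(terms, "fitted")
  chla_traj <- simulate_ude(representative, representative$x0, sample$t, drivers)
  windows <- detect_growth_windows(chla_traj[, "chla"], fitted[, "chla"],
                                   days = sample$t,
                                   min_days = config$min_window_days)
  ranking_df <- NULL
  if (nrow(windows) > 0) {
    ranking <- rank_contributions(terms, windows)
    ranking_df <- ranking_table(ranking, pattern = pattern)
    write.csv(ranking_df, out("contribution_ranking.csv"), row.names = FALSE)
    emit("contribution_ranking.csv")
  }

  # -- stage 7: evaluation
  mean_chla <- data.frame(day = t_grid, value = ensemble$mean_traj[, "chla"])
  base_chla <- data.frame(day = t_grid, value = base_curve$fit)
  metrics <- data.frame(
    pattern = pattern,
    comparison = c("train_ude_mean", "train_baseline", "baseline_vs_ude"),
    mse = c(
      mse_data_model(data.frame(day = train$day_of_year, value = train$chla), mean_chla),
      mse_data_model(data.frame(day = train$day_of_year, value = train$chla), base_chla),
      mse_model_model(base_chla, mean_chla)))
  if (!is.null(valid)) {
    vobs <- data.frame(day = valid$day_of_year, value = valid$chla)
    metrics <- rbind(metrics, data.frame(
      pattern = pattern,
      comparison = c("valid_ude_mean", "valid_baseline"),
      mse = c(mse_data_model(vobs, mean_chla), mse_data_model(vobs, base_chla))))
  }
  write.csv(metrics, out("metrics.csv"), row.names = FALSE)
  emit("metrics.csv")

  cfg_path <- out("config.yaml")
  cfg_save <- config
  cfg_save$outdir <- NULL   # runtime location, not part of the analysis identity
  save_config(cfg_save, cfg_path); emit("config.yaml")
  digests <- tools::md5sum(files)
  manifest <- list(seed = config$seed,
                   pattern = pattern,
                   config_digest = unname(tools::md5sum(cfg_path)),
                   penalty = as.numeric(penalty),
                   files = as.list(stats::setNames(unname(digests), basename(files))))
  jsonlite::write_json(manifest, out("manifest.json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(manifest)
}
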