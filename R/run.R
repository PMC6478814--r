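#' Run a configured batch simulation
#'
#' Config-driven wrapper around [simulate_unit()]: builds the grid, stimulus
#' and parameters from a configuration list (or YAML/JSON file path), runs
#' the simulation and writes spike trains, the stimulus and membrane
#' waveforms, and a JSON manifest (config echo, seeds, version, file
#' hashes). Identical configurations produce byte-identical outputs.
#'
#' Config keys: `type`; `grid` (`dt_s`, `duration_s`); `stimulus` (see
#' [stimulus_from_config()]); optional `params` overrides (e.g. `a_s`);
#' optional `noise` (`enabled`, `mech_sd_mm`, `neural_sd_v`, `cutoff_hz`,
#' `seed`); `n_units`; `write_waveforms`.
#'
#' @param config Named list or path to a YAML/JSON file.
#' @param outdir Output directory (created if missing).
#' @return Invisibly, a list with the `afferent_sim` result and the written
#'   file paths.
#' @export
run_simulate <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  grid <- time_grid(dt = config$grid$dt_s,
                    n_samples = round(config$grid$duration_s /
                                        config$grid$dt_s))
  spec <- config$stimulus
  spec$n_units <- config$n_units %||% spec$n_units %||% 1L
  stim <- stimulus_from_config(spec, grid)
  p <- do.call(afferent_params, c(list(type = config$type),
                                 config$params %||% list()))
  noise <- NULL
  if (isTRUE(config$noise$enabled)) {
    noise <- noise_params(
      mech_sd = config$noise$mech_sd_mm %||% 1e-4,
      neural_sd = config$noise$neural_sd_v %||% 0.010,
      cutoff_hz = config$noise$cutoff_hz %||% 1000,
      seed = config$noise$seed %||% config$seed %||% 1L)
  }
  sim <- simulate_unit(stim, p$receptor, p$fiber, noise)
  f_spikes <- file.path(outdir, "spikes.csv")
  write_spike_trains(sim$spikes, f_spikes, dt = grid$dt, t0 = grid$t0)
  files <- f_spikes
  if (isTRUE(config$write_waveforms %||% TRUE)) {
    f_x <- file.path(outdir, "stimulus.csv")
    f_va <- file.path(outdir, "membrane.csv")
    write_signal_block(sim$x, grid, f_x)
    write_signal_block(sim$v_a, grid, f_va)
    files <- c(files, f_x, f_va)
  }
  f_manifest <- file.path(outdir, "manifest.json")
  write_manifest(f_manifest, config, files)
  invisible(list(sim = sim, files = c(files, f_manifest)))
}

#' Run a configured rate-surface fit
#'
#' Wraps [fit_rate_model()]: reads a firing-rate dataset (CSV path or data
#' frame, or a list of data frames for repeats), fits the configured
#' afferent type, and writes the fitted parameter statistics as JSON plus
#' the per-repeat loss traces as CSV.
#'
#' @param data CSV path, `rate_dataset` data frame, or list of data frames.
#' @param config A [fit_config()], or a named list of [fit_config()]
#'   arguments.
#' @param outdir Output directory.
#' @return Invisibly, the `fit_result` and written file paths.
#' @export
run_fit <- function(data, config, outdir) {
  if (is.character(data)) data <- read_rate_dataset(data)
  if (!inherits(config, "fit_config")) config <- do.call(fit_config, config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  res <- fit_rate_model(data, config)
  f_json <- file.path(outdir, sprintf("fit_%s.json", res$type))
  jsonlite::write_json(list(
    type = res$type, n = res$n,
    theta_mean = as.list(res$theta_mean),
    theta_sd = as.list(res$theta_sd),
    J_final = res$J_final,
    fitting_precision_ips = res$fitting_precision,
    repeats = nrow(res$theta),
    iterations = res$config$iterations
  ), f_json, auto_unbox = TRUE, pretty = TRUE, digits = NA)
  f_loss <- file.path(outdir, sprintf("loss_%s.csv", res$type))
  loss <- data.frame(iteration = seq_along(res$loss_traces[[1]]),
                     do.call(cbind, res$loss_traces))
  names(loss)[-1] <- paste0("repeat", seq_along(res$loss_traces))
  utils::write.csv(loss, f_loss, row.names = FALSE)
  f_manifest <- file.path(outdir, sprintf("manifest_fit_%s.json", res$type))
  write_manifest(f_manifest, unclass(res$config), c(f_json, f_loss))
  invisible(list(fit = res, files = c(f_json, f_loss, f_manifest)))
}

#' Run the evaluation workflows
#'
#' Emits the per-type and composite frequency-threshold curves on a shared
#' log-spaced grid and, when the config names paired simulated/reference
#' spike-train CSV files, the jitter-based timing-precision report.
#'
#' Config keys: `freq_range_hz` (default `c(0.4, 800)`), `n_freq` (default
#' 60), optional `timing` (`simulated`, `reference` CSV paths, `window_s`,
#' `sd_grid_ms`, `n_jitter`, `seed`).
#'
#' @param config Named list or YAML/JSON path.
#' @param outdir Output directory.
#' @return Invisibly, the curves (and `jitter_result` if computed) plus
#'   file paths.
#' @export
run_evaluate <- function(config, outdir) {
  if (is.character(config)) config <- read_run_config(config)
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  fr <- config$freq_range_hz %||% c(0.4, 800)
  freq <- exp(seq(log(fr[1]), log(fr[2]),
                  length.out = config$n_freq %||% 60L))
  curves <- lapply(c("SA1", "RA1", "PC"), function(ty) {
    p <- afferent_params(ty)
    threshold_curve(p$receptor, p$fiber, freq, type = ty)
  })
  hm <- human_threshold(curves)
  all_curves <- do.call(rbind, c(curves, list(hm)))
  f_thr <- file.path(outdir, "threshold_curves.csv")
  utils::write.csv(all_curves, f_thr, row.names = FALSE)
  files <- f_thr
  jr <- NULL
  if (!is.null(config$timing)) {
    sim <- read_spike_trains(config$timing$simulated)
    ref <- read_spike_trains(config$timing$reference)
    jr <- timing_precision(sim$spikes, ref$spikes,
                           window = config$timing$window_s,
                           sd_grid = config$timing$sd_grid_ms %||% 1:10,
                           n_jitter = config$timing$n_jitter %||% 20L,
                           seed = config$timing$seed %||% config$seed %||% 1L)
    f_jit <- file.path(outdir, "timing_precision.json")
    jsonlite::write_json(list(precision_ms = jr$precision_ms,
                              in_range = jr$in_range,
                              curve = jr$curve),
                         f_jit, auto_unbox = TRUE, pretty = TRUE, digits = NA)
    files <- c(files, f_jit)
  }
  f_manifest <- file.path(outdir, "manifest_evaluate.json")
  write_manifest(f_manifest, config, files)
  invisible(list(curves = all_curves, timing = jr,
                 files = c(files, f_manifest)))
}
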