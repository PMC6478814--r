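#' Stimulus trace container
#'
#' A batch of indentation-depth waveforms on a shared time grid. Depth is in
#' mm, one row per unit.
#'
#' @param depth Numeric matrix (units x samples) or vector (one unit).
#' @param grid A [time_grid()]; `ncol(depth)` must equal `grid$n_samples`.
#' @return An object of class `stimulus_trace`.
#' @export
stimulus_trace <- function(depth, grid) {
  if (is.null(dim(depth))) depth <- matrix(depth, nrow = 1L)
  if (!all(is.finite(depth))) stop("stimulus depth must be finite")
  if (ncol(depth) != grid$n_samples)
    stop("depth has ", ncol(depth), " samples but grid has ", grid$n_samples)
  structure(list(depth = depth, grid = grid), class = "stimulus_trace")
}

#' @export
print.stimulus_trace <- function(x, ...) {
  cat(sprintf("<stimulus_trace> %d unit(s) x %d samples, dt = %g s, depth %.4g..%.4g mm\n",
              nrow(x$depth), ncol(x$depth), x$grid$dt,
              min(x$depth), max(x$depth)))
  invisible(x)
}

#' Sinusoidal vibration stimulus
#'
#' `depth(t) = offset + peak_amp * sin(2 pi freq (t - t0))`, starting at phase
#' zero at the first sample.
#'
#' @param grid A [time_grid()].
#' @param freq Vibration frequency (Hz, > 0).
#' @param peak_amp Peak amplitude (mm, >= 0).
#' @param offset Pre-indentation offset (mm).
#' @param n_units Number of identical units in the batch.
#' @return A [stimulus_trace()].
#' @examples
#' g <- time_grid(1e-4, 1000)
#' s <- make_sinusoid(g, freq = 20, peak_amp = 0.035)
#' @export
make_sinusoid <- function(grid, freq, peak_amp, offset = 0, n_units = 1L) {
  if (freq <= 0) stop("`freq` must be positive")
  if (peak_amp < 0) stop("`peak_amp` must be >= 0")
  t <- grid_times(grid) - grid$t0
  row <- offset + peak_amp * sin(2 * pi * freq * t)
  stimulus_trace(matrix(rep(row, each = n_units), nrow = n_units), grid)
}

#' Ramp-and-hold indentation stimulus
#'
#' Piecewise-linear trapezoid: ramp from 0 to `depth` over `ramp_time`, hold
#' at exactly `depth` for `hold_time`, release back to 0 over `release_time`.
#' The segments must fit inside the grid; the remainder is 0.
#'
#' @param grid A [time_grid()].
#' @param depth Plateau indentation depth (mm).
#' @param ramp_time,hold_time,release_time Segment durations (s, >= 0).
#' @param delay Time before ramp onset (s).
#' @param n_units Number of identical units.
#' @return A [stimulus_trace()].
#' @export
make_ramp_hold <- function(grid, depth, ramp_time, hold_time, release_time,
                           delay = 0, n_units = 1L) {
  durs <- c(delay, ramp_time, hold_time, release_time)
  if (any(durs < 0)) stop("durations must be >= 0")
  if (sum(durs) > grid_duration(grid) + 1e-12)
    stop("stimulus segments (", sum(durs), " s) exceed the grid length (",
         grid_duration(grid), " s)")
  t <- grid_times(grid) - grid$t0
  t1 <- delay; t2 <- t1 + ramp_time; t3 <- t2 + hold_time; t4 <- t3 + release_time
  row <- numeric(grid$n_samples)
  if (ramp_time > 0) {
    sel <- t >= t1 & t < t2
    row[sel] <- depth * (t[sel] - t1) / ramp_time
  }
  row[t >= t2 & t <= t3] <- depth
  if (release_time > 0) {
    sel <- t > t3 & t < t4
    row[sel] <- depth * (1 - (t[sel] - t3) / release_time)
  }
  stimulus_trace(matrix(rep(row, each = n_units), nrow = n_units), grid)
}

#' Descending (or arbitrary) amplitude staircase of sinusoid segments
#'
#' Concatenates equal-length constant-frequency sinusoid segments whose peak
#' amplitudes follow `levels` in order. The carrier phase is continuous across
#' segment boundaries so that the only transient is the amplitude change.
#'
#' @param grid A [time_grid()].
#' @param freq Carrier frequency (Hz, > 0).
#' @param levels Non-empty numeric vector of segment peak amplitudes (mm).
#' @param offset Pre-indentation offset (mm).
#' @param n_units Number of identical units.
#' @return A [stimulus_trace()].
#' @export
make_descending_staircase <- function(grid, freq, levels, offset = 0,
                                      n_units = 1L) {
  if (length(levels) == 0L) stop("`levels` must be non-empty")
  if (freq <= 0) stop("`freq` must be positive")
  t <- grid_times(grid) - grid$t0
  seg <- pmin(floor(t / (grid_duration(grid) / length(levels))) + 1L,
              length(levels))
  row <- offset + levels[seg] * sin(2 * pi * freq * t)
  stimulus_trace(matrix(rep(row, each = n_units), nrow = n_units), grid)
}

#' Default training-grid specification for an afferent class
#'
#' 20 log-spaced frequencies spanning the class's sensitive range and 10
#' linear peak amplitudes scaled to stay below rate saturation (noiseless
#' normalized rate <= 0.9 at the largest amplitude).
#'
#' @param type `"SA1"`, `"RA1"` or `"PC"`.
#' @param n_freq,n_amp Grid sizes.
#' @param f_range Frequency range (Hz); default 1-500 Hz (10-500 Hz for PC).
#' @return List with `freq` and `amp` vectors.
#' @export
default_rate_grid <- function(type = c("SA1", "RA1", "PC"), n_freq = 20L,
                              n_amp = 10L, f_range = NULL) {
  type <- match.arg(type)
  if (is.null(f_range)) f_range <- if (type == "PC") c(10, 500) else c(1, 500)
  freq <- exp(seq(log(f_range[1]), log(f_range[2]), length.out = n_freq))
  p <- afferent_params(type)
  gmax <- max(predict_rate(receptor_theta(p$receptor, p$fiber), x = 1,
                           f = freq, n = p$receptor$n))
  amp_max <- 0.9 / gmax
  list(freq = freq, amp = seq(amp_max / n_amp, amp_max, length.out = n_amp))
}

#' Synthetic firing-rate dataset
#'
#' Emulates a normalized firing-rate dataset of responses to sinusoidal
#' vibrations: for every (frequency, amplitude) grid point the noiseless
#' normalized rate is the model's closed-form rate response, and clipped
#' Gaussian noise is added, `y = clip(h(x, f) + e, 0, 1)`.
#'
#' @param params_by_type Named list of per-type parameter sets as returned by
#'   [afferent_params()]; defaults to the three fitted classes.
#' @param grids Named list (same names) of `list(freq, amp)` grids; defaults
#'   to [default_rate_grid()] per type.
#' @param noise_sd SD of the additive Gaussian rate noise (default 0.01).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return A `rate_dataset` data frame with columns `afferent_type`,
#'   `freq_hz`, `amp_mm`, `rate_norm`.
#' @examples
#' d <- synth_rate_dataset(noise_sd = 0, seed = 1)
#' head(d)
#' @export
synth_rate_dataset <- function(params_by_type = NULL, grids = NULL,
                               noise_sd = 0.01, seed = 1L) {
  if (noise_sd < 0) stop("`noise_sd` must be >= 0")
  if (is.null(params_by_type))
    params_by_type <- lapply(
      stats::setNames(nm = c("SA1", "RA1", "PC")), afferent_params)
  if (is.null(grids))
    grids <- lapply(stats::setNames(nm = names(params_by_type)),
                    default_rate_grid)
  out <- with_seed(seed, {
    rows <- lapply(names(params_by_type), function(ty) {
      p <- params_by_type[[ty]]
      g <- grids[[ty]]
      d <- expand.grid(freq_hz = g$freq, amp_mm = g$amp,
                       KEEP.OUT.ATTRS = FALSE)
      h <- predict_rate(receptor_theta(p$receptor, p$fiber),
                        x = d$amp_mm, f = d$freq_hz, n = p$receptor$n)
      if (any(h > 1))
        stop("amplitude grid for ", ty, " saturates the rate model (h > 1)")
      y <- h + stats::rnorm(nrow(d), 0, noise_sd)
      data.frame(afferent_type = ty, freq_hz = d$freq_hz, amp_mm = d$amp_mm,
                 rate_norm = pmin(pmax(y, 0), 1))
    })
    do.call(rbind, rows)
  })
  class(out) <- c("rate_dataset", "data.frame")
  out
}

#' Read / write a firing-rate dataset as CSV
#'
#' Columns: `afferent_type`, `freq_hz`, `amp_mm`, `rate_norm`.
#'
#' @param data A `rate_dataset` data frame.
#' @param path CSV file path.
#' @return `read_rate_dataset` returns the data frame; `write_rate_dataset`
#'   returns `path` invisibly.
#' @export
write_rate_dataset <- function(data, path) {
  utils::write.csv(as.data.frame(data), path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_rate_dataset
#' @export
read_rate_dataset <- function(path) {
  d <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("afferent_type", "freq_hz", "amp_mm", "rate_norm")
  miss <- setdiff(need, names(d))
  if (length(miss))
    stop("rate dataset is missing column(s): ", paste(miss, collapse = ", "))
  if (any(d$freq_hz <= 0)) stop("`freq_hz` must be positive")
  if (any(d$amp_mm < 0)) stop("`amp_mm` must be >= 0")
  class(d) <- c("rate_dataset", "data.frame")
  d
}

#' Build a stimulus from a configuration list
#'
#' Accepts the documented config keys (`type`, `freq_hz`, `amp_mm`,
#' `offset_mm`, `ramp_s`, `hold_s`, `release_s`, `delay_s`, `levels_mm`,
#' `n_units`) as parsed from YAML or JSON.
#'
#' @param spec Named list describing the stimulus.
#' @param grid A [time_grid()].
#' @return A [stimulus_trace()].
#' @export
stimulus_from_config <- function(spec, grid) {
  n_units <- spec$n_units %||% 1L
  switch(spec$type %||% stop("stimulus config needs a `type`"),
    sinusoid = make_sinusoid(grid, freq = spec$freq_hz,
                             peak_amp = spec$amp_mm,
                             offset = spec$offset_mm %||% 0,
                             n_units = n_units),
    ramp_hold = make_ramp_hold(grid, depth = spec$amp_mm,
                               ramp_time = spec$ramp_s,
                               hold_time = spec$hold_s,
                               release_time = spec$release_s,
                               delay = spec$delay_s %||% 0,
                               n_units = n_units),
    staircase = make_descending_staircase(grid, freq = spec$freq_hz,
                                          levels = unlist(spec$levels_mm),
                                          offset = spec$offset_mm %||% 0,
                                          n_units = n_units),
    stop("unknown stimulus type: ", spec$type)
  )
}
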