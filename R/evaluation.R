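#' Neural threshold at a frequency
#'
#' The minimum sinusoid peak amplitude (mm) at frequency `f` that drives the
#' unit above its firing threshold: `T(f) = V_L / (A_s |H(j 2 pi f)|)`.
#' Undefined (error) where the filter gain is zero, e.g. RA1/PC at DC.
#'
#' @param receptor A [receptor_params()].
#' @param fiber A [fiber_params()].
#' @param f Frequency (Hz, >= 0); vectorized.
#' @return Threshold(s) in mm.
#' @examples
#' p <- afferent_params("SA1")
#' threshold_at(p$receptor, p$fiber, 0)  # static threshold ~ 0.042 mm
#' @export
threshold_at <- function(receptor, fiber, f) {
  gain <- Mod(transfer_gain(receptor, f))
  if (any(gain == 0))
    stop("threshold undefined at f = ",
         paste(f[gain == 0], collapse = ", "),
         " Hz (zero filter gain)")
  fiber$v_l / (fiber$a_s * gain)
}

#' Lowest indentation threshold of a unit
#'
#' The threshold evaluated at the band-pass center frequency
#' `(f_BL + f_BH) / 2`, where the unit is near its most sensitive.
#'
#' @inheritParams threshold_at
#' @return Threshold in mm.
#' @export
lowest_threshold <- function(receptor, fiber) {
  threshold_at(receptor, fiber, (receptor$f_bl + receptor$f_bh) / 2)
}

#' Frequency-threshold curve
#'
#' Evaluates `T(f)` on a frequency grid; frequencies where the gain is zero
#' are returned as `NA` (flagged undefined) rather than an error.
#'
#' @inheritParams threshold_at
#' @param freq Frequency grid (Hz).
#' @param type Label stored with the curve.
#' @return A `threshold_curve` data frame with columns `freq_hz`,
#'   `threshold_mm`, `afferent_type`.
#' @export
threshold_curve <- function(receptor, fiber, freq,
                            type = receptor$type %||% NA_character_) {
  gain <- Mod(transfer_gain(receptor, freq))
  thr <- ifelse(gain > 0, fiber$v_l / (fiber$a_s * gain), NA_real_)
  out <- data.frame(freq_hz = freq, threshold_mm = thr,
                    afferent_type = type)
  class(out) <- c("threshold_curve", "data.frame")
  out
}

#' Composite (human) threshold curve
#'
#' The psychophysical detection threshold is modelled as the pointwise
#' minimum of the per-type afferent threshold curves on a shared frequency
#' grid; frequencies where a curve is undefined are ignored unless all
#' curves are undefined there.
#'
#' @param curves Non-empty list of `threshold_curve` data frames sharing one
#'   frequency grid.
#' @return A `threshold_curve` labelled `"human"`.
#' @export
human_threshold <- function(curves) {
  if (length(curves) == 0L) stop("`curves` must be non-empty")
  f0 <- curves[[1]]$freq_hz
  for (cu in curves)
    if (!isTRUE(all.equal(cu$freq_hz, f0)))
      stop("threshold curves must share one frequency grid")
  thr <- apply(vapply(curves, function(cu) cu$threshold_mm,
                      numeric(length(f0))), 1,
               function(v) if (all(is.na(v))) NA_real_ else min(v, na.rm = TRUE))
  out <- data.frame(freq_hz = f0, threshold_mm = thr,
                    afferent_type = "human")
  class(out) <- c("threshold_curve", "data.frame")
  out
}

#' ISI distance between two spike trains
#'
#' Time-averaged interspike-interval (ISI) distance: at every instant the
#' current ISI of each train is the interval between its surrounding spikes;
#' the instantaneous dissimilarity is the normalized ratio
#' `I(t) = x_a/x_b - 1` if `x_a <= x_b`, else `-(x_b/x_a - 1)`, and the
#' distance is the time average of `|I(t)|` over the window. It is zero for
#' identical trains, symmetric, and invariant to a common time shift.
#' Trains are edge-corrected with auxiliary spikes at the window bounds.
#'
#' @param a,b Numeric vectors of spike times (s).
#' @param window Length-2 numeric `c(t_start, t_end)` over which to average.
#' @return Dimensionless distance >= 0.
#' @examples
#' isi_distance(c(0, .1, .2), c(0, .2), window = c(0, .2))  # 0.5
#' @export
isi_distance <- function(a, b, window) {
  stopifnot(length(window) == 2L, window[2] > window[1])
  prep <- function(tr) {
    tr <- sort(tr[tr >= window[1] & tr <= window[2]])
    if (length(tr) == 0L)
      stop("a spike train has no spikes inside the window")
    # auxiliary spikes at the window edges (corrected-ISI convention)
    if (tr[1] > window[1]) tr <- c(window[1], tr)
    if (tr[length(tr)] > window[2] - 1e-12) tr[length(tr)] <- window[2]
    else tr <- c(tr, window[2])
    tr
  }
  ta <- prep(a); tb <- prep(b)
  brk <- sort(unique(c(ta, tb)))
  lo <- brk[-length(brk)]; hi <- brk[-1]
  mid <- (lo + hi) / 2
  cur_isi <- function(tr, t) {
    i <- findInterval(t, tr)
    i <- pmin(pmax(i, 1L), length(tr) - 1L)
    tr[i + 1L] - tr[i]
  }
  xa <- cur_isi(ta, mid); xb <- cur_isi(tb, mid)
  I <- ifelse(xa <= xb, xa / xb - 1, -(xb / xa - 1))
  sum(abs(I) * (hi - lo)) / (window[2] - window[1])
}

#' Jitter a spike train
#'
#' Adds independent zero-mean Gaussian perturbations (SD `sd_ms`
#' milliseconds) to every spike time and re-sorts.
#'
#' @param train Numeric vector of spike times (s).
#' @param sd_ms Jitter SD in milliseconds (>= 0).
#' @param seed Integer seed.
#' @return Jittered, sorted spike-time vector (s).
#' @export
jitter_spikes <- function(train, sd_ms, seed = 1L) {
  if (sd_ms < 0) stop("`sd_ms` must be >= 0")
  if (sd_ms == 0 || length(train) == 0L) return(train)
  with_seed(seed, sort(train + stats::rnorm(length(train), 0, sd_ms / 1000)))
}

#' Timing precision via jitter-matched ISI distance
#'
#' Quantifies how precisely simulated spike trains reproduce reference
#' trains: for each jitter SD the reference trains are jittered and the mean
#' difference `d(sim, ref) - d(jittered ref, ref)` over pairs and jitter
#' realizations is computed. A quadratic is fitted to the mean difference as
#' a function of SD; the smallest positive root inside the tested range is
#' the timing precision (the jitter level at which jittered references match
#' the references as well as the simulations do). Negative differences mean
#' the model is better than that jitter level.
#'
#' @param simulated,reference Lists of paired spike-time vectors (s).
#' @param window Length-2 analysis window (s).
#' @param sd_grid Jitter SDs in ms (default `1:10`).
#' @param n_jitter Jitter realizations per SD per train (default 20).
#' @param seed Master seed for the jitter draws.
#' @return An object of class `jitter_result`: data frame `curve`
#'   (`sd_ms`, `mean_diff`), quadratic coefficients `fit`, `precision_ms`
#'   (`NA` if the curve does not cross zero inside the range) and
#'   `in_range`.
#' @export
timing_precision <- function(simulated, reference, window, sd_grid = 1:10,
                             n_jitter = 20L, seed = 1L) {
  stopifnot(length(simulated) == length(reference),
            length(simulated) >= 1L)
  diffs <- vapply(sd_grid, function(sd_ms) {
    per_pair <- vapply(seq_along(simulated), function(i) {
      d_sim <- isi_distance(simulated[[i]], reference[[i]], window)
      d_jit <- vapply(seq_len(n_jitter), function(j) {
        jit <- jitter_spikes(reference[[i]], sd_ms,
                             seed = derive_seed(seed, i * 1000L + j +
                                                  round(sd_ms * 100)))
        isi_distance(jit, reference[[i]], window)
      }, numeric(1))
      d_sim - mean(d_jit)
    }, numeric(1))
    mean(per_pair)
  }, numeric(1))
  fit <- stats::lm(diffs ~ sd_grid + I(sd_grid^2))
  cf <- stats::coef(fit)
  roots <- polyroot(c(cf[1], cf[2], cf[3]))
  real <- Re(roots)[abs(Im(roots)) < 1e-8 * (1 + abs(Re(roots)))]
  cand <- sort(real[real > 0 & real <= max(sd_grid)])
  precision <- if (length(cand)) cand[1] else NA_real_
  structure(list(curve = data.frame(sd_ms = sd_grid, mean_diff = diffs),
                 fit = cf, precision_ms = precision,
                 in_range = !is.na(precision)),
            class = "jitter_result")
}

#' @export
print.jitter_result <- function(x, ...) {
  if (x$in_range)
    cat(sprintf("<jitter_result> timing precision %.2f ms\n", x$precision_ms))
  else
    cat("<jitter_result> no zero crossing inside the tested jitter range\n")
  invisible(x)
}
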