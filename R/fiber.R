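#' Mechanotransduction
#'
#' Linear conversion of the rectified mechanical signal (mm) to a driving
#' voltage (V): `v = a_s * q_m`.
#'
#' @param q_m Rectified receptor output (matrix or vector, mm, >= 0).
#' @param a_s Transducer coefficient (V/mm).
#' @return Driving voltage, same shape as `q_m`.
#' @export
transduce <- function(q_m, a_s) {
  if (any(q_m < 0)) stop("`q_m` must be non-negative (rectified)")
  a_s * q_m
}

#' Diode normalizer: drive voltage to normalized firing rate
#'
#' Models the neural threshold pair: no firing below the lower threshold
#' `v_l` (turn-on of the rectifying diode) and saturation at the upper clip
#' `v_h` (breakdown of the Zener diode). With the default `v_h` = 1 V the
#' output is the normalized firing rate in \[0, 1\]:
#' `v_nf = 0` where `v < v_l`, else `min(v, v_h) / v_h`.
#'
#' @param v Driving voltage (matrix or vector, V).
#' @param v_l Lower threshold (V), default 0.015.
#' @param v_h Upper clip (V), default 1.
#' @return Normalized firing-rate signal `v_nf`, same shape as `v`.
#' @export
normalize_drive <- function(v, v_l = 0.015, v_h = 1.0) {
  if (!(v_l < v_h)) stop("need v_l < v_h")
  out <- pmin(v, v_h) / v_h
  out[v < v_l] <- 0
  out
}

#' Pulse-frequency-modulation spike synthesizer
#'
#' Converts the normalized firing-rate signal into action potentials:
#' `v_nf` is sampled-and-held every `t_a` seconds into `v_s`; a triangular
#' carrier `v_f` (amplitude 0..1) runs at instantaneous frequency
#' `f_c = k_f * v_s` via a phase accumulator (phase is continuous across
#' hold boundaries); the comparator output `v_r` is 1 where `v_f > 0.5`; each
#' rising edge of `v_r` emits one spike onset and superposes the spike
#' template onto the membrane waveform `v_a` (baseline = resting potential;
#' overlapping templates add relative to rest).
#'
#' @param v_nf Normalized firing-rate block (units x samples), values in
#'   \[0, 1\].
#' @param fiber A [fiber_params()].
#' @param grid The [time_grid()] of `v_nf`; `dt` must resolve the spike
#'   period (`dt <= t_a / 10`).
#' @return A list with signal blocks `v_s`, `v_f`, `v_r`, `v_a`
#'   (units x samples) and `spikes`, a list of per-unit spike-onset time
#'   vectors (seconds, strictly increasing).
#' @examples
#' g <- time_grid(1e-4, 10000)
#' fib <- afferent_params("PC")$fiber
#' out <- synthesize_spikes(matrix(1, 1, g$n_samples), fib, g)
#' length(out$spikes[[1]])  # ~ k_f spikes in 1 s
#' @export
synthesize_spikes <- function(v_nf, fiber, grid) {
  stopifnot(inherits(fiber, "fiber_params"), inherits(grid, "time_grid"))
  if (is.null(dim(v_nf))) v_nf <- matrix(v_nf, nrow = 1L)
  if (ncol(v_nf) != grid$n_samples)
    stop("v_nf has ", ncol(v_nf), " samples, grid has ", grid$n_samples)
  dt <- grid$dt
  if (dt > fiber$t_a / 10)
    stop("dt = ", dt, " s is too coarse to resolve the spike period t_a = ",
         fiber$t_a, " s (need dt <= t_a/10)")
  nu <- nrow(v_nf); ns <- ncol(v_nf)

  hold_n <- max(1L, round(fiber$t_a / dt))
  hold_idx <- ((seq_len(ns) - 1L) %/% hold_n) * hold_n + 1L
  v_s <- v_nf[, hold_idx, drop = FALSE]

  # phase accumulator; phi in cycles, carrier frequency k_f * v_s
  dphi <- fiber$k_f * v_s * dt
  phi <- t(apply(dphi, 1L, cumsum))
  if (nu == 1L) phi <- matrix(phi, nrow = 1L)
  ph <- phi %% 1
  v_f <- ifelse(ph < 0.5, 2 * ph, 2 * (1 - ph))
  v_r <- (v_f > 0.5) * 1

  tpl <- fiber$template
  if (is.null(tpl)) tpl <- spike_template(dt, duration = fiber$t_a)
  if (!isTRUE(all.equal(tpl$dt, dt)))
    stop("spike template dt (", tpl$dt, ") does not match grid dt (", dt, ")")
  wav <- tpl$waveform - tpl$rest
  lw <- length(wav)

  t <- grid_times(grid)
  v_a <- matrix(tpl$rest, nu, ns)
  spikes <- vector("list", nu)
  for (u in seq_len(nu)) {
    edges <- which(v_r[u, ] == 1 & c(0, v_r[u, -ns]) == 0)
    spikes[[u]] <- t[edges]
    for (k in edges) {
      idx <- k:min(ns, k + lw - 1L)
      v_a[u, idx] <- v_a[u, idx] + wav[seq_along(idx)]
    }
  }
  list(v_s = v_s, v_f = v_f, v_r = v_r, v_a = v_a, spikes = spikes)
}

# First-order low-pass shaped Gaussian noise block (units x samples).
.shaped_noise <- function(nu, ns, sd, cutoff_hz, dt) {
  white <- matrix(stats::rnorm(nu * ns, 0, sd), nu, ns)
  if (cutoff_hz <= 0 || !is.finite(cutoff_hz)) return(white)
  wl <- 2 * pi * cutoff_hz
  ba <- .bilinear_ba(numeric(0), -wl, wl, dt)  # unity DC gain
  .iir_block(ba$b, ba$a, white)$y
}

#' Add mechanical noise to a stimulus
#'
#' Adds low-pass-shaped pseudo-Gaussian indentation noise (white SD
#' `mech_sd` mm through a first-order low-pass at `cutoff_hz`) to the
#' stimulus. Reproducible for a given `noise$seed`.
#'
#' @param x_in A [stimulus_trace()].
#' @param noise A [noise_params()].
#' @return A [stimulus_trace()] with noise added.
#' @export
add_mech_noise <- function(x_in, noise) {
  stopifnot(inherits(x_in, "stimulus_trace"), inherits(noise, "noise_params"))
  if (noise$mech_sd == 0) return(x_in)
  nz <- with_seed(derive_seed(noise$seed, 1L),
                  .shaped_noise(nrow(x_in$depth), ncol(x_in$depth),
                                noise$mech_sd, noise$cutoff_hz, x_in$grid$dt))
  stimulus_trace(x_in$depth + nz, x_in$grid)
}

#' Add neural noise to the membrane waveform
#'
#' Adds low-pass-shaped pseudo-Gaussian voltage noise (white SD `neural_sd`
#' V) to the action-potential waveform. Spike onsets are read from the
#' comparator before this stage, so neural noise never moves spike times.
#'
#' @param v_a Membrane waveform block (units x samples, V).
#' @param noise A [noise_params()].
#' @param dt Sampling interval of `v_a` (s).
#' @return Noisy waveform, same shape.
#' @export
add_neural_noise <- function(v_a, noise, dt) {
  stopifnot(inherits(noise, "noise_params"))
  if (is.null(dim(v_a))) v_a <- matrix(v_a, nrow = 1L)
  if (noise$neural_sd == 0) return(v_a)
  nz <- with_seed(derive_seed(noise$seed, 2L),
                  .shaped_noise(nrow(v_a), ncol(v_a), noise$neural_sd,
                                noise$cutoff_hz, dt))
  v_a + nz
}

#' End-to-end simulation of a batch of tactile units
#'
#' Runs the full electromechanical chain on an indentation stimulus:
#' optional mechanical noise, two-channel filter, rectifier, transducer,
#' diode normalizer, spike synthesizer and optional neural noise. All
#' intermediate stages are returned for inspection.
#'
#' @param x_in A [stimulus_trace()] (depth in mm).
#' @param receptor A [receptor_params()].
#' @param fiber A [fiber_params()].
#' @param noise A [noise_params()], or `NULL` for a noise-free run.
#' @return An object of class `afferent_sim`: a list with the stimulus `x`
#'   (after mechanical noise), stages `s_m`, `q_m`, `v`, `v_nf`, `v_s`,
#'   `v_f`, `v_r`, `v_a`, per-unit `spikes`, and the `grid`.
#' @examples
#' p <- afferent_params("SA1")
#' g <- time_grid(1e-4, 5000)
#' st <- make_ramp_hold(g, depth = 0.5, ramp_time = 0.05, hold_time = 0.3,
#'                      release_time = 0.05)
#' sim <- simulate_unit(st, p$receptor, p$fiber)
#' length(sim$spikes[[1]])
#' @export
simulate_unit <- function(x_in, receptor, fiber, noise = NULL) {
  stopifnot(inherits(x_in, "stimulus_trace"))
  if (!is.null(noise)) x_in <- add_mech_noise(x_in, noise)
  real <- discretize(receptor, x_in$grid$dt)
  s_m <- filter_apply(real, x_in)
  q_m <- rectify(s_m, receptor$w)
  v <- transduce(q_m, fiber$a_s)
  v_nf <- normalize_drive(v, fiber$v_l, fiber$v_h)
  syn <- synthesize_spikes(v_nf, fiber, x_in$grid)
  v_a <- syn$v_a
  if (!is.null(noise)) v_a <- add_neural_noise(v_a, noise, x_in$grid$dt)
  structure(list(x = x_in$depth, s_m = s_m, q_m = q_m, v = v, v_nf = v_nf,
                 v_s = syn$v_s, v_f = syn$v_f, v_r = syn$v_r, v_a = v_a,
                 spikes = syn$spikes, grid = x_in$grid),
            class = "afferent_sim")
}

#' @export
print.afferent_sim <- function(x, ...) {
  ns <- vapply(x$spikes, length, integer(1))
  cat(sprintf("<afferent_sim> %d unit(s) x %d samples (%g s); spikes/unit: %s\n",
              nrow(x$x), ncol(x$x), grid_duration(x$grid),
              paste(utils::head(ns, 8), collapse = ", ")))
  invisible(x)
}
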