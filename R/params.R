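#' Receptor (two-channel filter) parameters
#'
#' The receptor of a tactile unit is modelled as a two-channel linear filter:
#' a band-pass channel selecting the dynamic component of skin indentation and
#' a low-pass channel selecting the static component,
#' \deqn{H(s) = \frac{\sum_k K_{bk} s^k}{s + 2\pi f_{BL}}
#'       \left(\frac{2\pi f_{BH}}{s + 2\pi f_{BH}}\right)^{n+1}
#'       + K_u \frac{2\pi f_L}{s + 2\pi f_L},}
#' followed by a rectifier with negative-lobe weight `w`.
#'
#' @param kb Numeric vector of band-pass numerator weights `K_b1..K_bn`
#'   (the k-th weight multiplies the k-th derivative of the input).
#' @param ku Low-pass channel weight (dimensionless; 0 for RA1/PC).
#' @param f_bl,f_bh Lower and upper band-pass cutoff frequencies (Hz).
#' @param f_l Low-pass cutoff frequency (Hz; 0 for RA1/PC).
#' @param w Negative contribution of the rectifier (>= 0; 0 for SA1).
#' @param type Optional afferent class label ("SA1", "RA1", "PC").
#' @return An object of class `receptor_params`.
#' @seealso [afferent_params()] for the fitted per-type defaults.
#' @export
receptor_params <- function(kb, ku = 0, f_bl, f_bh, f_l = 0, w = 0,
                            type = NA_character_) {
  kb <- as.numeric(kb)
  n <- length(kb)
  if (n < 1L || n > 3L) stop("`kb` must have 1 to 3 entries (band-pass order)")
  if (w < 0) stop("rectifier weight `w` must be >= 0")
  if (any(kb != 0)) {
    if (!(f_bh >= f_bl) || !(f_bl > 0))
      stop("band-pass cutoffs need f_bh >= f_bl > 0 when any kb != 0")
  }
  structure(list(kb = kb, ku = ku, n = n, f_bl = f_bl, f_bh = f_bh,
                 f_l = f_l, w = w, type = type),
            class = "receptor_params")
}

#' @export
print.receptor_params <- function(x, ...) {
  cat(sprintf("<receptor_params%s> n = %d\n",
              if (is.na(x$type)) "" else paste0(" ", x$type), x$n))
  cat("  kb  :", paste(signif(x$kb, 4), collapse = ", "), "\n")
  cat(sprintf("  ku = %g, f_bl = %g Hz, f_bh = %g Hz, f_l = %g Hz, w = %g\n",
              x$ku, x$f_bl, x$f_bh, x$f_l, x$w))
  invisible(x)
}

#' Afferent-fiber parameters
#'
#' Constants of the transducer, diode normalizer and spike synthesizer.
#' The transducer converts the rectified mechanical signal to volts with gain
#' `a_s` (V/mm). The normalizer gates drive below `v_l` and clips at `v_h`;
#' with `v_h` = 1 V the drive in volts is numerically the normalized firing
#' rate. The synthesizer samples the normalized rate every `t_a` seconds and
#' emits one spike per cycle of a triangular carrier of instantaneous
#' frequency `k_f * v_s`.
#'
#' @param a_s Transducer coefficient (V/mm).
#' @param k_f Maximum firing rate (impulses per second).
#' @param v_l Lower threshold voltage (V); default 0.015 (15 mV, the distance
#'   from resting to threshold potential of a typical neuron).
#' @param v_h Upper clip voltage (V); default 1.
#' @param t_a Sample-and-hold period and spike-template duration (s);
#'   default 0.004.
#' @param template Spike template, see [spike_template()]. `NULL` means the
#'   default template is built lazily at the simulation grid's `dt`.
#' @return An object of class `fiber_params`.
#' @export
fiber_params <- function(a_s, k_f, v_l = 0.015, v_h = 1.0, t_a = 0.004,
                         template = NULL) {
  if (!(v_l > 0 && v_l < v_h)) stop("need 0 < v_l < v_h")
  if (k_f <= 0) stop("`k_f` must be positive")
  if (t_a <= 0) stop("`t_a` must be positive")
  structure(list(a_s = a_s, k_f = k_f, v_l = v_l, v_h = v_h, t_a = t_a,
                 template = template),
            class = "fiber_params")
}

#' Noise model parameters
#'
#' Mechanical noise is zero-mean Gaussian displacement noise (SD `mech_sd`
#' mm) added to the stimulus; neural noise is Gaussian voltage noise (SD
#' `neural_sd` V) added to the membrane waveform. Both are shaped by a
#' first-order low-pass filter with cutoff `cutoff_hz` before being added.
#'
#' @param mech_sd Mechanical noise SD in mm (default 1e-4, i.e. 0.1 um).
#' @param neural_sd Neural noise SD in volts (default 0.010).
#' @param cutoff_hz Low-pass cutoff of the noise-shaping filter (Hz).
#' @param seed Integer seed making noise realizations reproducible.
#' @return An object of class `noise_params`.
#' @export
noise_params <- function(mech_sd = 1e-4, neural_sd = 0.010,
                         cutoff_hz = 1000, seed = 1L) {
  if (mech_sd < 0 || neural_sd < 0) stop("noise SDs must be >= 0")
  structure(list(mech_sd = mech_sd, neural_sd = neural_sd,
                 cutoff_hz = cutoff_hz, seed = as.integer(seed)),
            class = "noise_params")
}

# Fitted per-type parameter means. Band-pass order is 1/2/3 for SA1/RA1/PC;
# the low-pass channel exists only for SA1; the rectifier keeps part of the
# negative lobe only for RA1/PC.
.type_defaults <- list(
  SA1 = list(kb = 0.205, ku = 0.094, f_bl = 8.01, f_bh = 10.03,
             f_l = 100.20, w = 0, a_s = 3.80, k_f = 180),
  RA1 = list(kb = c(0.232, 0.0031), ku = 0, f_bl = 60.10, f_bh = 80.09,
             f_l = 0, w = 0.015, a_s = 44.00, k_f = 200),
  PC  = list(kb = c(0, 0.128, 0.00111), ku = 0, f_bl = 80.40, f_bh = 220.02,
             f_l = 0, w = 0.212, a_s = 0.36, k_f = 300)
)

#' Default parameters for an afferent class
#'
#' Returns the fitted mean receptor and fiber parameters for one of the three
#' major tactile afferent classes: slowly adapting type 1 (`"SA1"`), rapidly
#' adapting type 1 (`"RA1"`) or Pacinian (`"PC"`). Individual fields can be
#' overridden through `...` (e.g. `afferent_params("SA1", a_s = 4)`).
#'
#' @param type One of `"SA1"`, `"RA1"`, `"PC"`.
#' @param ... Named overrides for any of `kb`, `ku`, `f_bl`, `f_bh`, `f_l`,
#'   `w`, `a_s`, `k_f`, `v_l`, `v_h`, `t_a`.
#' @return A list with elements `receptor` ([receptor_params()]) and
#'   `fiber` ([fiber_params()]).
#' @examples
#' p <- afferent_params("PC")
#' p$receptor
#' @export
afferent_params <- function(type = c("SA1", "RA1", "PC"), ...) {
  type <- match.arg(type)
  d <- .type_defaults[[type]]
  ov <- list(...)
  extra <- list(v_l = 0.015, v_h = 1.0, t_a = 0.004)
  for (nm in names(ov)) {
    if (nm %in% names(d)) d[[nm]] <- ov[[nm]]
    else if (nm %in% names(extra)) extra[[nm]] <- ov[[nm]]
    else stop("unknown parameter override: ", nm)
  }
  list(
    receptor = receptor_params(kb = d$kb, ku = d$ku, f_bl = d$f_bl,
                               f_bh = d$f_bh, f_l = d$f_l, w = d$w,
                               type = type),
    fiber = fiber_params(a_s = d$a_s, k_f = d$k_f, v_l = extra$v_l,
                         v_h = extra$v_h, t_a = extra$t_a)
  )
}

#' Action-potential template
#'
#' A parameterized spike waveform sampled on the simulation grid: resting
#' potential, a depolarization peak, an after-hyperpolarization undershoot and
#' return to rest, connected by smooth cosine segments. Durations are in
#' seconds and potentials in volts.
#'
#' @param dt Sampling interval (s).
#' @param duration Total template duration (s), normally equal to the spike
#'   period `t_a`.
#' @param rest,peak,undershoot Resting, peak and undershoot potentials (V).
#' @param t_peak,t_undershoot Times of the peak and the undershoot (s).
#' @return An object of class `spike_template` holding the sampled waveform.
#' @examples
#' tpl <- spike_template(dt = 1e-4)
#' plot(tpl$t, tpl$waveform * 1e3, type = "l", ylab = "mV", xlab = "s")
#' @export
spike_template <- function(dt, duration = 0.004, rest = -0.070, peak = 0.040,
                           undershoot = -0.090, t_peak = 0.001,
                           t_undershoot = 0.0025) {
  stopifnot(dt > 0, duration > 0, t_peak < t_undershoot, t_undershoot < duration)
  t <- seq(0, duration, by = dt)
  knots_t <- c(0, t_peak, t_undershoot, duration)
  knots_v <- c(rest, peak, undershoot, rest)
  v <- numeric(length(t))
  for (i in seq_len(3)) {
    sel <- t >= knots_t[i] & t <= knots_t[i + 1]
    u <- (t[sel] - knots_t[i]) / (knots_t[i + 1] - knots_t[i])
    v[sel] <- knots_v[i] + (knots_v[i + 1] - knots_v[i]) * (1 - cos(pi * u)) / 2
  }
  structure(list(t = t, waveform = v, dt = dt, duration = duration,
                 rest = rest, peak = peak, undershoot = undershoot),
            class = "spike_template")
}

#' @export
print.spike_template <- function(x, ...) {
  cat(sprintf(
    "<spike_template> %g ms, rest %g mV, peak %g mV, undershoot %g mV (%d samples)\n",
    x$duration * 1e3, x$rest * 1e3, x$peak * 1e3, x$undershoot * 1e3,
    length(x$waveform)))
  invisible(x)
}
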