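#' Frequency response of the two-channel receptor filter
#'
#' Evaluates the receptor transfer function at `s = j 2 pi f`:
#' the band-pass channel
#' `(sum_k K_bk s^k) / (s + 2 pi f_BL) * (2 pi f_BH / (s + 2 pi f_BH))^(n+1)`
#' plus the low-pass channel `K_u * 2 pi f_L / (s + 2 pi f_L)`.
#'
#' @param params A [receptor_params()].
#' @param f Frequency (Hz, >= 0); vectorized.
#' @return Complex gain vector; take `Mod()` for the magnitude.
#' @examples
#' sa1 <- afferent_params("SA1")$receptor
#' Mod(transfer_gain(sa1, c(0, 9.02, 100)))
#' @export
transfer_gain <- function(params, f) {
  stopifnot(inherits(params, "receptor_params"))
  if (any(f < 0)) stop("`f` must be >= 0")
  s <- 1i * 2 * pi * f
  n <- params$n
  bp <- rep(0 + 0i, length(f))
  if (any(params$kb != 0)) {
    num <- rep(0 + 0i, length(f))
    for (k in seq_len(n)) num <- num + params$kb[k] * s^k
    bp <- num / (s + 2 * pi * params$f_bl) *
      (2 * pi * params$f_bh / (s + 2 * pi * params$f_bh))^(n + 1)
  }
  lp <- rep(0 + 0i, length(f))
  if (params$ku != 0 && params$f_l > 0) {
    lp <- params$ku * 2 * pi * params$f_l / (s + 2 * pi * params$f_l)
  }
  bp + lp
}

# Bilinear-transform a strictly proper analog rational function given as
# zeros/poles/gain into digital b, a coefficients.
.bilinear_ba <- function(zeros, poles, gain, dt) {
  zpg <- signal::bilinear(Sz = zeros, Sp = poles, Sg = gain, T = dt)
  arma <- signal::as.Arma(zpg)
  list(b = Re(arma$b), a = Re(arma$a))
}

#' Discrete-time realization of the receptor filter
#'
#' Converts the continuous-time two-channel filter to a digital filter at
#' sampling interval `dt` via the bilinear transform, as two parallel IIR
#' sections (band-pass and low-pass) with explicit per-unit state so that
#' filtering can be resumed across successive signal blocks.
#'
#' @param params A [receptor_params()].
#' @param dt Sampling interval (s). The sampling rate must resolve the band
#'   edge: `1/dt >= 4 * f_bh`.
#' @return An object of class `filter_realization` (an environment holding
#'   coefficients and filter state). Pass it to [filter_apply()]; reset state
#'   with [reset_state()].
#' @export
discretize <- function(params, dt) {
  stopifnot(inherits(params, "receptor_params"))
  if (dt <= 0) stop("`dt` must be positive")
  if (any(params$kb != 0) && 1 / dt < 4 * params$f_bh)
    stop("sampling rate 1/dt = ", 1 / dt,
         " Hz violates the condition 1/dt >= 4 * f_bh = ",
         4 * params$f_bh, " Hz")
  n <- params$n
  bpf <- NULL
  if (any(params$kb != 0)) {
    # numerator sum kb_k s^k = s * (kb_1 + kb_2 s + ...); trim trailing zeros
    coefs <- params$kb
    deg <- max(which(coefs != 0))
    coefs <- coefs[seq_len(deg)]
    zeros <- c(0, if (deg > 1) polyroot(coefs))
    poles <- c(-2 * pi * params$f_bl, rep(-2 * pi * params$f_bh, n + 1))
    gain <- coefs[deg] * (2 * pi * params$f_bh)^(n + 1)
    bpf <- .bilinear_ba(zeros, poles, gain, dt)
  }
  lpf <- NULL
  if (params$ku != 0 && params$f_l > 0) {
    wl <- 2 * pi * params$f_l
    lpf <- .bilinear_ba(numeric(0), -wl, params$ku * wl, dt)
  }
  e <- new.env(parent = emptyenv())
  e$params <- params
  e$dt <- dt
  e$bpf <- bpf
  e$lpf <- lpf
  e$state_bpf <- NULL
  e$state_lpf <- NULL
  class(e) <- "filter_realization"
  e
}

#' @export
print.filter_realization <- function(x, ...) {
  cat(sprintf("<filter_realization> dt = %g s (fs = %g Hz), %s%s\n",
              x$dt, 1 / x$dt,
              if (is.null(x$bpf)) "no band-pass" else
                sprintf("band-pass order %d", length(x$bpf$a) - 1L),
              if (is.null(x$lpf)) "" else " + low-pass order 1"))
  invisible(x)
}

#' Reset the internal state of a filter realization
#'
#' @param realization A [discretize()] result.
#' @return The realization, invisibly.
#' @export
reset_state <- function(realization) {
  realization$state_bpf <- NULL
  realization$state_lpf <- NULL
  invisible(realization)
}

# Direct-form II transposed IIR over a (units x samples) block.
# state: units x order matrix; returns list(y, state).
.iir_block <- function(b, a, x, state = NULL) {
  m <- max(length(a), length(b)) - 1L
  b <- c(b, rep(0, m + 1L - length(b)))
  a <- c(a, rep(0, m + 1L - length(a)))
  if (a[1] != 1) { b <- b / a[1]; a <- a / a[1] }
  nu <- nrow(x); ns <- ncol(x)
  if (is.null(state)) state <- matrix(0, nu, m)
  if (nrow(state) != nu) stop("filter state was initialized for ",
                              nrow(state), " unit(s), got ", nu)
  y <- matrix(0, nu, ns)
  for (k in seq_len(ns)) {
    xk <- x[, k]
    yk <- b[1] * xk + state[, 1]
    if (m > 1L) for (j in seq_len(m - 1L))
      state[, j] <- state[, j + 1L] + b[j + 1L] * xk - a[j + 1L] * yk
    state[, m] <- b[m + 1L] * xk - a[m + 1L] * yk
    y[, k] <- yk
  }
  list(y = y, state = state)
}

#' Apply the receptor filter to a stimulus block
#'
#' Runs the discretized two-channel filter causally over a stimulus trace and
#' returns the summed channel output `s_m` (units x samples). Filter state is
#' carried inside the realization across successive calls, so a long signal
#' can be processed in consecutive blocks.
#'
#' @param realization A [discretize()] result.
#' @param x_in A [stimulus_trace()] or a numeric matrix (units x samples)
#'   sampled at the realization's `dt`.
#' @return Numeric matrix `s_m` (units x samples).
#' @export
filter_apply <- function(realization, x_in) {
  stopifnot(inherits(realization, "filter_realization"))
  x <- if (inherits(x_in, "stimulus_trace")) {
    if (!isTRUE(all.equal(x_in$grid$dt, realization$dt)))
      stop("stimulus dt (", x_in$grid$dt, ") does not match realization dt (",
           realization$dt, ")")
    x_in$depth
  } else if (is.matrix(x_in)) x_in else matrix(x_in, nrow = 1L)
  s_m <- matrix(0, nrow(x), ncol(x))
  if (!is.null(realization$bpf)) {
    r <- .iir_block(realization$bpf$b, realization$bpf$a, x,
                    realization$state_bpf)
    realization$state_bpf <- r$state
    s_m <- s_m + r$y
  }
  if (!is.null(realization$lpf)) {
    r <- .iir_block(realization$lpf$b, realization$lpf$a, x,
                    realization$state_lpf)
    realization$state_lpf <- r$state
    s_m <- s_m + r$y
  }
  s_m
}

#' Rectify the filter output
#'
#' Half-wave rectification keeping a weighted fraction of the negative lobe:
#' `q_m = max(s_m, 0) - w * min(s_m, 0)`, which is non-negative everywhere.
#' For a sinusoid of amplitude A the time average of `q_m` is
#' `A (1 + w) / pi`, the factor that links the time-domain pipeline to the
#' closed-form rate response.
#'
#' @param s_m Numeric matrix or vector (filter output, mm).
#' @param w Negative-contribution weight (>= 0; 0 for SA1).
#' @return Rectified signal `q_m`, same shape as `s_m`.
#' @export
rectify <- function(s_m, w) {
  if (w < 0) stop("`w` must be >= 0")
  pmax(s_m, 0) - w * pmin(s_m, 0)
}
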