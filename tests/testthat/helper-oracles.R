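# Independent oracle: term-by-term complex evaluation of the two-channel
# transfer function, written without any package internals.
oracle_gain <- function(kb, ku, fbl, fbh, fl, f) {
  n <- length(kb)
  vapply(f, function(fi) {
    s <- complex(imaginary = 2 * pi * fi)
    num <- sum(kb * s^(seq_len(n)))
    bp <- num / (s + 2 * pi * fbl) * (2 * pi * fbh / (s + 2 * pi * fbh))^(n + 1)
    lp <- if (ku != 0 && fl > 0) ku * 2 * pi * fl / (s + 2 * pi * fl) else 0 + 0i
    Mod(bp + lp)
  }, numeric(1))
}

# Raw fitted-mean parameter tables used by the oracles (kept separate from
# the package's own defaults on purpose).
tab_sa1 <- list(kb = 0.205, ku = 0.094, fbl = 8.01, fbh = 10.03, fl = 100.20,
                a_s = 3.80, w = 0, k_f = 180)
tab_ra1 <- list(kb = c(0.232, 0.0031), ku = 0, fbl = 60.10, fbh = 80.09,
                fl = 0, a_s = 44.00, w = 0.015, k_f = 200)
tab_pc <- list(kb = c(0, 0.128, 0.00111), ku = 0, fbl = 80.40, fbh = 220.02,
               fl = 0, a_s = 0.36, w = 0.212, k_f = 300)

# Steady-state amplitude of a sampled sinusoid by projection onto the
# quadrature pair at frequency f (exact, independent of sampling phase).
fit_amplitude <- function(y, t, f) {
  X <- cbind(sin(2 * pi * f * t), cos(2 * pi * f * t))
  cf <- stats::coef(stats::lm(y ~ X))
  sqrt(cf[2]^2 + cf[3]^2)
}
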