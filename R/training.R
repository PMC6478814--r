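#' Parameter vector for rate-surface fitting
#'
#' The trainable parameter array is ordered
#' `[K_b1..K_bn, K_u, f_BL, f_BH, f_L, A_s, w]`. `receptor_theta()` packs a
#' receptor/fiber parameter pair into this vector; `theta_to_params()`
#' unpacks a fitted vector back into parameter objects.
#'
#' @param receptor A [receptor_params()].
#' @param fiber A [fiber_params()] (supplies `a_s`).
#' @return Named numeric vector of length `n + 6`.
#' @export
receptor_theta <- function(receptor, fiber) {
  stopifnot(inherits(receptor, "receptor_params"))
  th <- c(receptor$kb, receptor$ku, receptor$f_bl, receptor$f_bh,
          receptor$f_l, fiber$a_s, receptor$w)
  names(th) <- theta_names(receptor$n)
  th
}

#' @rdname receptor_theta
#' @param n Band-pass order (number of `K_b` weights).
#' @export
theta_names <- function(n) {
  c(paste0("kb", seq_len(n)), "ku", "f_bl", "f_bh", "f_l", "a_s", "w")
}

#' @rdname receptor_theta
#' @param theta Parameter vector ordered as above.
#' @param type Afferent class label for the resulting objects.
#' @param k_f Maximum firing rate for the fiber object.
#' @export
theta_to_params <- function(theta, n, type = NA_character_, k_f = 200) {
  list(
    receptor = receptor_params(kb = theta[seq_len(n)], ku = theta[n + 1],
                               f_bl = theta[n + 2], f_bh = theta[n + 3],
                               f_l = theta[n + 4], w = theta[n + 6],
                               type = type),
    fiber = fiber_params(a_s = theta[n + 5], k_f = k_f)
  )
}

# |H(j 2 pi f)| directly from a theta vector, without parameter validation
# (intermediate optimizer iterates may sit on constraint boundaries).
.theta_gain <- function(theta, f, n) {
  kb <- theta[seq_len(n)]
  ku <- theta[n + 1]; fbl <- theta[n + 2]; fbh <- theta[n + 3]
  fl <- theta[n + 4]
  s <- 1i * 2 * pi * f
  bp <- rep(0 + 0i, length(f))
  if (any(kb != 0)) {
    num <- rep(0 + 0i, length(f))
    for (k in seq_len(n)) num <- num + kb[k] * s^k
    bp <- num / (s + 2 * pi * fbl) *
      (2 * pi * fbh / (s + 2 * pi * fbh))^(n + 1)
  }
  lp <- if (ku != 0 && fl > 0) ku * 2 * pi * fl / (s + 2 * pi * fl) else 0
  Mod(bp + lp)
}

#' Closed-form normalized rate response to a sinusoid
#'
#' The model's normalized firing rate for a sinusoidal indentation of peak
#' amplitude `x` (mm) at frequency `f` (Hz):
#' `h = A_s * |H(j 2 pi f)| * x * (1 + w) / pi`,
#' the time-averaged rectified, transduced filter output.
#'
#' @param theta Parameter vector (see [receptor_theta()]).
#' @param x Peak amplitude (mm, >= 0); vectorized with `f`.
#' @param f Frequency (Hz, > 0).
#' @param n Band-pass order.
#' @return Normalized rate(s).
#' @export
predict_rate <- function(theta, x, f, n) {
  if (any(x < 0)) stop("`x` must be >= 0")
  if (any(f <= 0)) stop("`f` must be positive")
  a_s <- theta[n + 5]; w <- theta[n + 6]
  unname(a_s * .theta_gain(theta, f, n) * x * (1 + w) / pi)
}

#' Sum-of-squares training loss
#'
#' `J = 1/2 * sum_i (h(x_i, f_i) - y_i)^2` over a firing-rate dataset.
#'
#' @param theta Parameter vector.
#' @param data A `rate_dataset` data frame (columns `freq_hz`, `amp_mm`,
#'   `rate_norm`) restricted to one afferent type.
#' @param n Band-pass order.
#' @return Scalar loss `J >= 0`.
#' @export
rate_loss <- function(theta, data, n) {
  if (nrow(data) == 0L) stop("`data` must be non-empty")
  h <- predict_rate(theta, data$amp_mm, data$freq_hz, n)
  0.5 * sum((h - data$rate_norm)^2)
}

#' Central-difference gradient of the training loss
#'
#' `dJ/dtheta_k ~ (J(theta + h e_k) - J(theta - h e_k)) / (2 h)` with a
#' per-coordinate step `h = max(1e-6, 1e-4 |theta_k|)` unless `fd_step` is
#' given. Constrained (non-free) coordinates get gradient exactly 0.
#'
#' @inheritParams rate_loss
#' @param free Logical mask of trainable coordinates; `NULL` means all free.
#' @param fd_step Fixed finite-difference step, or `NULL` for the relative
#'   default.
#' @return Gradient vector, same length as `theta`.
#' @export
grad_central <- function(theta, data, n, free = NULL, fd_step = NULL) {
  if (!is.null(fd_step) && fd_step <= 0) stop("`fd_step` must be positive")
  p <- length(theta)
  if (is.null(free)) free <- rep(TRUE, p)
  g <- numeric(p)
  for (k in which(free)) {
    h <- if (is.null(fd_step)) max(1e-6, 1e-4 * abs(theta[k])) else fd_step
    tp <- theta; tp[k] <- theta[k] + h
    tm <- theta; tm[k] <- theta[k] - h
    g[k] <- (rate_loss(tp, data, n) - rate_loss(tm, data, n)) / (2 * h)
  }
  g
}

#' Trainable-coordinate mask for an afferent class
#'
#' `K_u` and `f_L` are constrained to 0 for RA1 and PC; `w` is constrained
#' to 0 for SA1.
#'
#' @param type `"SA1"`, `"RA1"` or `"PC"`.
#' @param n Band-pass order (defaults to the class's standard order 1/2/3).
#' @return Logical vector of length `n + 6`.
#' @export
theta_free_mask <- function(type = c("SA1", "RA1", "PC"), n = NULL) {
  type <- match.arg(type)
  if (is.null(n)) n <- switch(type, SA1 = 1L, RA1 = 2L, PC = 3L)
  free <- rep(TRUE, n + 6L)
  names(free) <- theta_names(n)
  if (type == "SA1") free["w"] <- FALSE
  else free[c("ku", "f_l")] <- FALSE
  free
}

#' Fitting configuration
#'
#' @param type Afferent class; fixes the constraint mask and default order.
#' @param n Band-pass order (default 1/2/3 for SA1/RA1/PC).
#' @param alpha Fixed step size of the quasi-Newton update (default 0.55).
#' @param iterations Number of update iterations (default 1100).
#' @param repeats Number of repeat fits (default 10); repeats differ by the
#'   noise seed of their datasets.
#' @param fd_step Central-difference step (`NULL` = relative default).
#' @param normalize Feature-scale `rate_norm` to \[0, 1\] before fitting
#'   (default `TRUE`).
#' @param step_cap Cap on the scaled step norm per iteration (default 0.25).
#' @param init_spreads Deterministic multi-start factors for the band-edge
#'   initialization (the best final loss is kept).
#' @param seed Master seed recorded with the result.
#' @return A `fit_config` list.
#' @export
fit_config <- function(type = c("SA1", "RA1", "PC"), n = NULL, alpha = 0.55,
                       iterations = 1100L, repeats = 10L, fd_step = NULL,
                       normalize = TRUE, step_cap = 0.25,
                       init_spreads = c(1.25, 1.5, 2, 3), seed = 1L) {
  type <- match.arg(type)
  if (alpha <= 0) stop("`alpha` must be positive")
  if (iterations < 1L) stop("`iterations` must be >= 1")
  if (is.null(n)) n <- switch(type, SA1 = 1L, RA1 = 2L, PC = 3L)
  structure(list(type = type, n = as.integer(n), alpha = alpha,
                 iterations = as.integer(iterations),
                 repeats = as.integer(repeats), fd_step = fd_step,
                 normalize = normalize, step_cap = step_cap,
                 init_spreads = init_spreads, seed = as.integer(seed)),
            class = "fit_config")
}

# One quasi-Newton run in scaled coordinates.
# scale maps scaled z to raw theta = z * scale.
.fit_single <- function(data, n, free, z0, scale, alpha, iters, fd_step,
                        step_cap) {
  p <- length(z0)
  i_bl <- n + 2L; i_bh <- n + 3L
  proj <- function(z) {
    z[!free] <- 0
    z[z < 0] <- 0
    if (z[i_bh] < z[i_bl]) z[c(i_bl, i_bh)] <- z[c(i_bh, i_bl)]
    z
  }
  lossz <- function(z) rate_loss(z * scale, data, n)
  gradz <- function(z) {
    g <- numeric(p)
    for (k in which(free)) {
      h <- if (is.null(fd_step)) max(1e-6, 1e-4 * abs(z[k])) else fd_step
      zp <- z; zp[k] <- z[k] + h
      zm <- z; zm[k] <- z[k] - h
      g[k] <- (lossz(zp) - lossz(zm)) / (2 * h)
    }
    g
  }
  z <- proj(z0)
  H <- diag(p)
  g <- gradz(z)
  J_cur <- lossz(z)
  z_best <- z; J_best <- J_cur
  Jtr <- numeric(iters)
  first <- TRUE
  for (it in seq_len(iters)) {
    step <- -alpha * drop(H %*% g)
    nst <- sqrt(sum(step^2))
    if (nst > step_cap) step <- step * step_cap / nst
    zn <- proj(z + step)
    gn <- gradz(zn)
    Jn <- lossz(zn)
    if (!is.finite(Jn))
      stop("fit diverged (non-finite loss) at iteration ", it)
    if (Jn > J_cur) {
      # a fixed-step quasi-Newton pass can destabilize once the curvature
      # model goes stale; restart the metric from the identity
      H <- diag(p)
      first <- TRUE
    } else {
      s <- zn - z; y <- gn - g
      sy <- sum(s * y)
      if (sy > 1e-10 * sqrt(sum(s * s) * sum(y * y))) {
        if (first) { H <- diag(p) * sy / sum(y * y); first <- FALSE }
        rho <- 1 / sy
        V <- diag(p) - rho * outer(s, y)
        H <- V %*% H %*% t(V) + rho * outer(s, s)
      }
    }
    z <- zn; g <- gn; J_cur <- Jn
    if (Jn < J_best) { J_best <- Jn; z_best <- zn }
    Jtr[it] <- Jn
  }
  list(theta = z_best * scale, J = Jtr, J_best = J_best)
}

#' Fit the receptor/transducer parameters to firing-rate data
#'
#' Minimizes the sum-of-squares loss of the closed-form rate response over
#' the parameter vector `[K_b1..K_bn, K_u, f_BL, f_BH, f_L, A_s, w]` with a
#' quasi-Newton (BFGS) update applied at a fixed step size `alpha` on the
#' central-difference gradient. After every update, constrained entries are
#' projected to 0, negative entries are clipped to 0 and the band edges are
#' reordered so `f_BL <= f_BH`. Coordinates are internally rescaled
#' (frequencies by the geometric-mean data frequency) and each fit is run
#' from a small deterministic set of band-edge initializations, keeping the
#' lowest final loss. Because the rate equation depends on the gains only
#' through the product `A_s * K_b * (1 + w)`, individual gains are not
#' separately identifiable; the frequency parameters are.
#'
#' @param data A `rate_dataset` data frame for one afferent type, or a list
#'   of such data frames (one per repeat; repeats normally differ by the
#'   noise seed used to generate them).
#' @param config A [fit_config()].
#' @return An object of class `fit_result`: per-repeat parameter matrix
#'   `theta`, `theta_mean`, `theta_sd`, list of `loss_traces`, final losses
#'   `J_final`, and `fitting_precision` (ips) when the trace is long enough
#'   and `k_f` is known for the configured type.
#' @export
fit_rate_model <- function(data, config) {
  stopifnot(inherits(config, "fit_config"))
  if (is.data.frame(data)) data <- rep(list(data), config$repeats)
  if (length(data) != config$repeats)
    config$repeats <- length(data)
  n <- config$n
  free <- theta_free_mask(config$type, n)
  p <- n + 6L
  fits <- vector("list", config$repeats)
  for (r in seq_len(config$repeats)) {
    d <- data[[r]]
    if ("afferent_type" %in% names(d)) {
      d <- d[d$afferent_type == config$type, , drop = FALSE]
    }
    if (nrow(d) == 0L) stop("no records for type ", config$type,
                            " in repeat ", r)
    if (config$normalize) {
      rng <- range(d$rate_norm)
      if (diff(rng) > 0)
        d$rate_norm <- (d$rate_norm - rng[1]) / diff(rng)
    }
    fgeo <- exp(mean(log(d$freq_hz)))
    scale <- c((2 * pi * fgeo)^-(seq_len(n) - 1L), 1, fgeo, fgeo, fgeo, 1, 1)
    best <- NULL
    for (sp in config$init_spreads) {
      z0 <- c(rep(0.5, n), 1, 1 / sp, sp, 1, 1, 1)
      fit <- .fit_single(d, n, free, z0, scale, config$alpha,
                         config$iterations, config$fd_step, config$step_cap)
      if (is.null(best) || fit$J_best < best$J_best)
        best <- fit
    }
    fits[[r]] <- best
  }
  theta <- do.call(rbind, lapply(fits, `[[`, "theta"))
  colnames(theta) <- theta_names(n)
  traces <- lapply(fits, `[[`, "J")
  k_f <- .type_defaults[[config$type]]$k_f
  m <- nrow(data[[1]])
  fp <- if (config$iterations >= 1100L)
    vapply(traces, fitting_precision, numeric(1), m = m, k_f = k_f) else NULL
  structure(list(theta = theta,
                 theta_mean = colMeans(theta),
                 theta_sd = if (nrow(theta) > 1L)
                   apply(theta, 2, stats::sd)
                 else stats::setNames(numeric(ncol(theta)),
                                      colnames(theta)),
                 loss_traces = traces,
                 J_final = vapply(traces, function(j) j[length(j)],
                                  numeric(1)),
                 fitting_precision = fp,
                 config = config, n = n, type = config$type),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result %s> %d repeat(s), %d iterations\n",
              x$type, nrow(x$theta), x$config$iterations))
  tab <- rbind(mean = x$theta_mean, sd = x$theta_sd)
  print(signif(tab, 4))
  if (!is.null(x$fitting_precision))
    cat(sprintf("fitting precision: %.3g ips (mean over repeats)\n",
                mean(x$fitting_precision)))
  invisible(x)
}

#' Fitting precision from a loss trace
#'
#' Root-mean-squared rate error expressed in impulses per second:
#' `K_f * mean(sqrt(J_t / m))` over iterations 1000 to 1100 of the loss
#' trace.
#'
#' @param loss_trace Numeric vector of per-iteration losses, length >= 1100.
#' @param m Training-set size.
#' @param k_f Maximum firing rate of the afferent type (ips).
#' @return Fitting precision in ips.
#' @export
fitting_precision <- function(loss_trace, m, k_f) {
  if (length(loss_trace) < 1100L)
    stop("loss trace has ", length(loss_trace),
         " iterations; need >= 1100")
  k_f * mean(sqrt(loss_trace[1000:1100] / m))
}

#' Synthetic per-repeat training datasets for one afferent class
#'
#' Generates `n_seeds` single-type firing-rate datasets on the class's
#' default grid, differing only in the noise seed (derived from
#' `master_seed`). The result is ready to pass to [fit_rate_model()].
#'
#' @param type `"SA1"`, `"RA1"` or `"PC"`.
#' @param n_seeds Number of datasets (default 10).
#' @param noise_sd Rate noise SD (default 0.01).
#' @param master_seed Seed from which per-repeat seeds are derived.
#' @return List of `rate_dataset` data frames.
#' @export
synth_rate_repeats <- function(type = c("SA1", "RA1", "PC"), n_seeds = 10L,
                               noise_sd = 0.01, master_seed = 1L) {
  type <- match.arg(type)
  params <- stats::setNames(list(afferent_params(type)), type)
  grids <- stats::setNames(list(default_rate_grid(type)), type)
  lapply(seq_len(n_seeds), function(k)
    synth_rate_dataset(params, grids, noise_sd = noise_sd,
                       seed = derive_seed(master_seed, k)))
}
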