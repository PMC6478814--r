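sa1_theta <- function() {
  p <- afferent_params("SA1")
  receptor_theta(p$receptor, p$fiber)
}

test_that("the closed-form rate response is linear in amplitude", {
  th <- sa1_theta()
  expect_equal(predict_rate(th, 0, 10, 1), 0)
  x <- c(0.01, 0.05, 0.2)
  expect_equal(predict_rate(th, 2 * x, 9, 1), 2 * predict_rate(th, x, 9, 1))
  # frozen derived value: SA1 means, f = 9.02 Hz, x = 0.05 mm
  expect_equal(predict_rate(th, 0.05, 9.02, 1), 0.0102260577,
               tolerance = 1e-8)
  expect_error(predict_rate(th, -1, 9, 1), ">= 0")
  expect_error(predict_rate(th, 1, 0, 1), "positive")
})

test_that("the training loss is a half sum of squares", {
  th <- sa1_theta()
  d <- synth_rate_dataset(list(SA1 = afferent_params("SA1")),
                          list(SA1 = default_rate_grid("SA1")),
                          noise_sd = 0)
  expect_equal(rate_loss(th, d, 1), 0)

  # single record with h = 0.5, y = 0.3 -> J = 0.02
  x_half <- 0.5 / predict_rate(th, 1, 9.02, 1)
  d1 <- data.frame(freq_hz = 9.02, amp_mm = x_half, rate_norm = 0.3)
  expect_equal(rate_loss(th, d1, 1), 0.02)

  # permutation invariance
  dn <- synth_rate_dataset(list(SA1 = afferent_params("SA1")),
                           list(SA1 = default_rate_grid("SA1")),
                           noise_sd = 0.05, seed = 3)
  expect_equal(rate_loss(th, dn, 1),
               rate_loss(th, dn[sample(nrow(dn)), ], 1))
  expect_error(rate_loss(th, dn[0, ], 1), "non-empty")
})

test_that("central-difference gradients match analytic derivatives", {
  th <- sa1_theta()
  d <- synth_rate_dataset(list(SA1 = afferent_params("SA1")),
                          list(SA1 = default_rate_grid("SA1")),
                          noise_sd = 0)
  g0 <- grad_central(th, d, 1)
  expect_lt(max(abs(g0)), 1e-4)   # near-stationary at the perfect fit

  # one-parameter oracle: J(a_s) = 1/2 sum (a_s * c_i - y_i)^2 with
  # c_i = |H| x (1+w)/pi, so dJ/da_s = sum c_i (a_s c_i - y_i)
  ci <- predict_rate(th, d$amp_mm, d$freq_hz, 1) / th["a_s"]
  y <- 0.8 * th["a_s"] * ci
  dd <- data.frame(freq_hz = d$freq_hz, amp_mm = d$amp_mm, rate_norm = y)
  g <- grad_central(th, dd, 1)
  analytic <- sum(ci * (th["a_s"] * ci - y))
  expect_equal(unname(g[length(th) - 1]), unname(analytic),
               tolerance = 1e-6)

  # constrained coordinates get exactly zero gradient
  free <- theta_free_mask("RA1")
  th_ra <- receptor_theta(afferent_params("RA1")$receptor,
                          afferent_params("RA1")$fiber)
  d_ra <- synth_rate_dataset(list(RA1 = afferent_params("RA1")),
                             list(RA1 = default_rate_grid("RA1")),
                             noise_sd = 0.02, seed = 2)
  g_ra <- grad_central(th_ra, d_ra, 2, free = free)
  expect_identical(unname(g_ra[names(free) == "ku"]), 0)
  expect_identical(unname(g_ra[names(free) == "f_l"]), 0)
  expect_error(grad_central(th, d, 1, fd_step = -1), "positive")
})

test_that("central-difference gradient agrees with a finer-step oracle", {
  set.seed(11)
  d <- synth_rate_dataset(list(SA1 = afferent_params("SA1")),
                          list(SA1 = default_rate_grid("SA1")),
                          noise_sd = 0.05, seed = 8)
  for (i in 1:5) {
    th <- sa1_theta() * runif(7, 0.5, 1.5)
    g1 <- grad_central(th, d, 1)
    g2 <- vapply(seq_along(th), function(k) {  # finer central difference
      h <- max(1e-9, 1e-7 * abs(th[k]))
      tp <- th; tp[k] <- th[k] + h; tm <- th; tm[k] <- th[k] - h
      (rate_loss(tp, d, 1) - rate_loss(tm, d, 1)) / (2 * h)
    }, numeric(1))
    expect_equal(g1, g2, tolerance = 1e-4)
  }
})

test_that("fitting noise-free data recovers the generating filter", {
  for (ty in c("SA1", "RA1", "PC")) {
    p <- afferent_params(ty)
    th_true <- receptor_theta(p$receptor, p$fiber)
    n <- p$receptor$n
    d0 <- synth_rate_dataset(stats::setNames(list(p), ty),
                             stats::setNames(list(default_rate_grid(ty)), ty),
                             noise_sd = 0)
    cfg <- fit_config(ty, repeats = 1, normalize = FALSE)
    res <- fit_rate_model(d0, cfg)
    tm <- res$theta_mean
    for (nm in c("f_bl", "f_bh", "f_l")) {
      if (th_true[nm] > 0)
        expect_equal(unname(tm[nm]), unname(th_true[nm]), tolerance = 0.05,
                     info = paste(ty, nm))
    }
    # gains are identifiable only through the product A_s * K_b * (1 + w)
    k_lead <- paste0("kb", n)
    expect_equal(unname(tm["a_s"] * tm[k_lead] * (1 + tm["w"])),
                 unname(th_true["a_s"] * th_true[k_lead] *
                          (1 + th_true["w"])),
                 tolerance = 0.05, info = ty)
    # the loss decreased and constrained entries stayed at zero
    tr <- res$loss_traces[[1]]
    expect_lt(tr[length(tr)], tr[1])
    free <- theta_free_mask(ty, n)
    expect_true(all(res$theta[, !free] == 0))
  }
})

test_that("degenerate all-zero targets drive the gain to zero", {
  d <- synth_rate_dataset(list(SA1 = afferent_params("SA1")),
                          list(SA1 = default_rate_grid("SA1")),
                          noise_sd = 0)
  d$rate_norm <- 0
  cfg <- fit_config("SA1", repeats = 1, iterations = 300,
                    normalize = FALSE)
  res <- fit_rate_model(d, cfg)
  h_fit <- predict_rate(res$theta[1, ], d$amp_mm, d$freq_hz, 1)
  expect_lt(max(h_fit), 1e-3)
  expect_lt(res$J_final, 1e-6)
})

test_that("fits are deterministic given identical inputs", {
  ds <- synth_rate_repeats("SA1", n_seeds = 2, noise_sd = 0.01,
                           master_seed = 5)
  cfg <- fit_config("SA1", iterations = 150)
  r1 <- fit_rate_model(ds, cfg)
  r2 <- fit_rate_model(ds, cfg)
  expect_identical(r1$theta, r2$theta)
  expect_identical(r1$loss_traces, r2$loss_traces)
})

test_that("fitting precision is the K_f-scaled tail RMS of the loss", {
  expect_equal(fitting_precision(numeric(1200), m = 50, k_f = 180), 0)
  m <- 40; k_f <- 200
  expect_equal(fitting_precision(rep(m / k_f^2, 1100), m, k_f), 1)
  expect_error(fitting_precision(numeric(900), 10, 180), ">= 1100")

  # with rate noise sd, the converged tail RMS is ~ K_f * sd / sqrt(2)
  ds <- synth_rate_repeats("RA1", n_seeds = 1, noise_sd = 0.01,
                           master_seed = 2)
  res <- fit_rate_model(ds, fit_config("RA1", repeats = 1))
  expect_gt(res$fitting_precision, 0.5 * 200 * 0.01)
  expect_lt(res$fitting_precision, 2 * 200 * 0.01)
})
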