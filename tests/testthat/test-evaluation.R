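test_that("neural thresholds follow T(f) = V_L / (A_s |H|)", {
  sa1 <- afferent_params("SA1")
  # frozen oracle: static threshold from the fitted means,
  # 0.015 / (3.80 * 0.094)
  expect_equal(threshold_at(sa1$receptor, sa1$fiber, 0), 0.0419932811,
               tolerance = 1e-9)
  ra1 <- afferent_params("RA1")
  expect_error(threshold_at(ra1$receptor, ra1$fiber, 0), "undefined")

  # doubling the transducer gain halves the threshold everywhere
  sa1_hot <- afferent_params("SA1", a_s = 2 * 3.80)
  f <- c(1, 5, 9.02, 50, 200)
  expect_equal(threshold_at(sa1_hot$receptor, sa1_hot$fiber, f),
               threshold_at(sa1$receptor, sa1$fiber, f) / 2)
})

test_that("the lowest threshold sits at the band center", {
  sa1 <- afferent_params("SA1")
  expect_equal(lowest_threshold(sa1$receptor, sa1$fiber),
               threshold_at(sa1$receptor, sa1$fiber, (8.01 + 10.03) / 2))
  # frozen oracle value for SA1: V_L / (A_s |H(j 2 pi 9.02)|)
  expect_equal(lowest_threshold(sa1$receptor, sa1$fiber), 0.0233454985,
               tolerance = 1e-9)
  # PC: dense-grid oracle over the band; the center value matches the
  # dense evaluation exactly at 150.21 Hz (frozen: 1.019807e-4 mm)
  pc <- afferent_params("PC")
  expect_equal(lowest_threshold(pc$receptor, pc$fiber), 1.019806849e-4,
               tolerance = 1e-7)
  fg <- seq(80.40, 220.02, length.out = 500)
  expect_equal(lowest_threshold(pc$receptor, pc$fiber),
               threshold_at(pc$receptor, pc$fiber, 150.21),
               tolerance = 1e-6)
  expect_gte(lowest_threshold(pc$receptor, pc$fiber),
             min(threshold_at(pc$receptor, pc$fiber, fg)))
})

test_that("per-type threshold curves reproduce the band structure", {
  freq <- exp(seq(log(0.5), log(600), length.out = 50))
  curves <- lapply(c("SA1", "RA1", "PC"), function(ty) {
    p <- afferent_params(ty)
    threshold_curve(p$receptor, p$fiber, freq, type = ty)
  })
  tab <- vapply(curves, function(cu) cu$threshold_mm, numeric(50))
  # SA1 is the most sensitive channel at low frequency, PC at high
  lo <- freq <= 3; hi <- freq >= 100
  expect_true(all(apply(tab[lo, , drop = FALSE], 1, which.min) == 1))
  expect_true(all(apply(tab[hi, , drop = FALSE], 1, which.min) == 3))

  hm <- human_threshold(curves)
  expect_equal(hm$freq_hz, freq)
  for (cu in curves) {
    ok <- !is.na(cu$threshold_mm)
    expect_true(all(hm$threshold_mm[ok] <= cu$threshold_mm[ok] + 1e-15))
  }
  expect_equal(human_threshold(curves[1])$threshold_mm,
               curves[[1]]$threshold_mm)
  expect_error(human_threshold(list()), "non-empty")
})

test_that("sinusoids straddling T(f) gate spiking on and off", {
  for (ty in c("SA1", "RA1", "PC")) {
    p <- afferent_params(ty)
    fc <- (p$receptor$f_bl + p$receptor$f_bh) / 2
    for (f in c(fc, 2 * fc)) {
      Tf <- threshold_at(p$receptor, p$fiber, f)
      # resolve the carrier, the band edge and the 4 ms spike period
      dt <- 1 / max(50 * f, 8 * p$receptor$f_bh, 2500)
      g <- time_grid(dt, ceiling(max(0.5, 30 / f) / dt))
      below <- simulate_unit(make_sinusoid(g, f, 0.9 * Tf),
                             p$receptor, p$fiber)
      above <- simulate_unit(make_sinusoid(g, f, 1.5 * Tf),
                             p$receptor, p$fiber)
      expect_equal(length(below$spikes[[1]]), 0,
                   info = sprintf("%s below T at %g Hz", ty, f))
      expect_gt(length(above$spikes[[1]]), 0)
    }
  }
})

test_that("the ISI distance is a proper spike-train metric", {
  # hand-integrated oracle: constant ISIs 100 ms vs 200 ms -> |0.5| always
  expect_equal(isi_distance(c(0, 0.1, 0.2), c(0, 0.2), c(0, 0.2)), 0.5)
  a <- sort(runif(30)); b <- sort(runif(25))
  w <- c(0, 1)
  expect_equal(isi_distance(a, a, w), 0)
  expect_equal(isi_distance(a, b, w), isi_distance(b, a, w))
  expect_gte(isi_distance(a, b, w), 0)
  # invariance under a common shift of both trains and the window
  expect_equal(isi_distance(a + 5, b + 5, w + 5), isi_distance(a, b, w))
  expect_error(isi_distance(numeric(0), b, w), "no spikes")
})

test_that("jitter is seeded and has the half-normal mean displacement", {
  tr <- seq(0, 10, by = 0.01)
  expect_identical(jitter_spikes(tr, 0, seed = 1), tr)
  j1 <- jitter_spikes(tr, 3, seed = 4)
  expect_identical(j1, jitter_spikes(tr, 3, seed = 4))
  expect_false(identical(j1, jitter_spikes(tr, 3, seed = 5)))
  # mean |displacement| of sd-jitter is sd * sqrt(2/pi)
  big <- seq(0, 1e4) * 1.0
  jb <- jitter_spikes(big, 5, seed = 7)
  disp <- sort(jb) - big  # displacements (re-sorting at this density is rare)
  expect_equal(mean(abs(disp)) * 1000, 5 * sqrt(2 / pi), tolerance = 0.05)
})

test_that("timing precision recovers a known jitter level", {
  # reference trains from the model itself; "simulated" trains are the
  # references jittered at 5 ms, so the recovered precision must be ~5 ms
  p <- afferent_params("RA1")
  g <- time_grid(1e-4, 20000)  # 2 s
  st <- make_sinusoid(g, 30, 0.05, n_units = 1)
  ref1 <- simulate_unit(st, p$receptor, p$fiber)$spikes[[1]]
  refs <- lapply(1:5, function(i) ref1)
  sims <- lapply(1:5, function(i) jitter_spikes(ref1, 5, seed = 100 + i))
  jr <- timing_precision(sims, refs, window = c(0.1, 1.9),
                         n_jitter = 50, seed = 3)
  expect_true(jr$in_range)
  expect_equal(jr$precision_ms, 5, tolerance = 0.2)

  # a perfect model sits below the smallest tested jitter level
  jr0 <- timing_precision(refs, refs, window = c(0.1, 1.9),
                          n_jitter = 10, seed = 3)
  expect_true(all(jr0$curve$mean_diff <= 0))

  # mean distance to the reference grows with jitter SD on average
  d_by_sd <- vapply(c(1, 4, 9), function(sd_ms) {
    mean(vapply(1:20, function(j)
      isi_distance(jitter_spikes(ref1, sd_ms, seed = j), ref1,
                   c(0.1, 1.9)), numeric(1)))
  }, numeric(1))
  expect_true(all(diff(d_by_sd) > 0))
})
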