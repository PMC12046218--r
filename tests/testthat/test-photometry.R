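test_that("an exact linear channel relation corrects to identically zero", {
  set.seed(1)
  f405 <- 80 + cumsum(rnorm(200, 0, 0.1))
  rec <- photometry_recording((0:199) / 100, 2 * f405 + 1, f405, 100)
  ct <- isosbestic_correct(rec)
  expect_equal(ct$fit_slope, 2, tolerance = 1e-10)
  expect_equal(ct$fit_intercept, 1, tolerance = 1e-8)
  expect_equal(max(abs(ct$dff)), 0, tolerance = 1e-10)
  # stored coefficients reproduce dff exactly
  expect_equal(ct$dff, rec$f465 - (ct$fit_slope * rec$f405 + ct$fit_intercept))
})

test_that("degenerate and malformed recordings are rejected with context", {
  t <- (0:99) / 100
  expect_error(isosbestic_correct(
    photometry_recording(t, rnorm(100), rep(5, 100), 100)), "degenerate")
  f465 <- rnorm(100); f465[37] <- NaN
  expect_error(isosbestic_correct(
    photometry_recording(t, f465, rnorm(100), 100)), "index 37")
  expect_error(photometry_recording(t, rnorm(100), rnorm(100), 250),
               "inconsistent")
})

test_that("the reference fit matches the closed-form normal equations", {
  for (seed in 1:25) {
    set.seed(seed)
    p <- photometry_sim_params(artifact_sd = 1, white_noise_sd = 0.2,
                               seed = seed)
    sim <- simulate_photometry(p)
    ct <- isosbestic_correct(sim$recording)
    x <- sim$recording$f405; y <- sim$recording$f465
    slope0 <- sum((x - mean(x)) * (y - mean(y))) / sum((x - mean(x))^2)
    int0 <- mean(y) - slope0 * mean(x)
    expect_equal(ct$fit_slope, slope0, tolerance = 1e-6)
    expect_equal(ct$fit_intercept, int0, tolerance = 1e-6)
  }
})

test_that("shared-artifact correction removes most of the artifact variance", {
  p <- photometry_sim_params(duration = 60, seed = 99)
  sim <- simulate_photometry(p)
  ct <- isosbestic_correct(sim$recording)
  t <- sim$recording$time
  bleach <- p$bleach_amplitude_465 * exp(-t / p$bleach_tau_465)
  raw <- sim$recording$f465 - bleach - p$baseline_465
  expect_lt(var(ct$dff), 0.1 * var(raw))
})

test_that("correcting the corrected trace again finds nothing left to remove", {
  set.seed(3)
  f405 <- 80 + cumsum(rnorm(500, 0, 0.05))
  f465 <- 1.5 * f405 + 2
  rec <- photometry_recording((0:499) / 100, f465, f405, 100)
  ct <- isosbestic_correct(rec)
  rec2 <- photometry_recording(rec$time, ct$dff, f405, 100)
  expect_lt(abs(isosbestic_correct(rec2)$fit_slope), 1e-6)
})

test_that("epoch z-scoring uses window statistics with the sample sd", {
  tr <- make_trace(dff = c(1, 2, 3, 10, 20), fs = 1)
  zt <- zscore_epoch(tr, c(0, 2))
  expect_equal(zt$z[1:3], c(-1, 0, 1))
  expect_equal(zt$z[4], (10 - 2) / 1)
  set.seed(4)
  tr2 <- make_trace(dff = rnorm(1000))
  whole <- zscore_epoch(tr2, c(0, 9.99))
  expect_equal(mean(whole$z), 0, tolerance = 1e-9)
  expect_equal(sd(whole$z), 1, tolerance = 1e-9)
  expect_error(zscore_epoch(make_trace(dff = rep(2, 100)), c(0, 0.5)),
               "constant")
})

test_that("z-scoring is invariant to positive affine transforms of dff", {
  set.seed(5)
  dff <- cumsum(rnorm(400))
  for (ab in list(c(2, 1), c(0.3, -7), c(10, 100))) {
    z1 <- zscore_epoch(make_trace(dff = dff), c(1, 3))$z
    z2 <- zscore_epoch(make_trace(dff = ab[1] * dff + ab[2]), c(1, 3))$z
    expect_equal(z1, z2, tolerance = 1e-9)
  }
})

test_that("distinct epochs produce distinct normalizations, matching recomputation", {
  set.seed(6)
  dff <- cumsum(rnorm(800, 0, 0.3))
  tr <- make_trace(dff = dff)
  zA <- zscore_epoch(tr, c(0, 2))
  zB <- zscore_epoch(tr, c(5, 7))
  iA <- which(tr$time >= 0 & tr$time <= 2)
  iB <- which(tr$time >= 5 & tr$time <= 7)
  expect_equal(zA$z, (dff - mean(dff[iA])) / sd(dff[iA]), tolerance = 1e-12)
  expect_equal(zB$z, (dff - mean(dff[iB])) / sd(dff[iB]), tolerance = 1e-12)
  expect_false(isTRUE(all.equal(zA$z, zB$z)))
})

test_that("peak detection finds isolated maxima and nothing on flat traces", {
  z <- rep(0, 1001)
  z[401:601] <- 3 * (1 - abs(-100:100) / 100)  # triangular pulse, peak at t = 5
  tr <- make_trace(z = z)
  pk <- detect_peaks(tr, c(0, 10))
  expect_identical(nrow(pk), 1L)
  expect_equal(pk$time, 5)
  expect_equal(pk$amplitude, 3)
  expect_identical(nrow(detect_peaks(make_trace(z = rep(0, 500)), c(0, 4))), 0L)
})

test_that("peaks of two injected kernels are recovered near truth", {
  fs <- 100
  t <- (0:2999) / fs
  set.seed(8)
  z <- 2 * test_kernel(t - 10) + 4 * test_kernel(t - 20) + rnorm(3000, 0, 0.05)
  tr <- make_trace(z = z)
  pk <- detect_peaks(tr, c(5, 28), min_prominence = 0.5)
  expect_identical(nrow(pk), 2L)
  tpk <- 0.1 * 0.8 / 0.7 * log(8)  # kernel peak delay
  # brute-force oracle: argmax in a window around each injected time
  for (i in 1:2) {
    truth_t <- c(10, 20)[i] + tpk
    win <- which(t > truth_t - 1 & t < truth_t + 1)
    expect_lt(abs(pk$time[i] - t[win][which.max(z[win])]), 1 / fs + 1e-12)
    expect_lt(abs(pk$amplitude[i] - c(2, 4)[i]) / c(2, 4)[i], 0.10)
  }
})

test_that("plateau ties break to the earliest sample and separation thins peaks", {
  z <- c(0, 1, 2, 2, 2, 1, 0, 0, 1, 2.5, 1, 0)
  tr <- make_trace(z = z, fs = 10)
  pk <- detect_peaks(tr, c(0, 1.1), min_prominence = 0.5, min_separation = 0)
  expect_equal(pk$time[1], 0.2)  # first sample of the flat top
  pk2 <- detect_peaks(tr, c(0, 1.1), min_prominence = 0.5, min_separation = 2)
  expect_identical(nrow(pk2), 1L)
  expect_equal(pk2$amplitude, 2.5)  # larger peak wins the separation contest
})

test_that("baseline peak takes the largest pre-onset transient, with ramp fallback", {
  fs <- 100
  t <- (0:999) / fs
  z <- 1.5 * test_kernel(t - (5 - 0.4 - 0.1 * 0.8 / 0.7 * log(8)))
  bp <- baseline_peak(make_trace(z = z), stimulus_onset = 5)
  expect_false(bp$fallback)
  expect_equal(bp$amplitude, 1.5, tolerance = 0.01)
  ramp <- make_trace(z = seq(0, 2, length.out = 1000))
  bp2 <- baseline_peak(ramp, stimulus_onset = 5)
  expect_true(bp2$fallback)
  imax <- max(which(ramp$time < 5))
  expect_equal(bp2$amplitude, ramp$z[imax])
  expect_error(baseline_peak(make_trace(z = rnorm(200)), stimulus_onset = 0.5),
               "first")
})

test_that("baseline statistic matches a brute-force window scan over seeds", {
  for (seed in 1:100) {
    set.seed(seed)
    tr <- make_trace(z = rnorm(500))
    bp <- baseline_peak(tr, stimulus_onset = 3)
    idx <- which(tr$time >= 2 & tr$time < 3)
    z <- tr$z
    # oracle: scan interior local maxima with >= 0.5 prominence directly
    best <- -Inf
    for (j in idx) {
      if (j > 1 && j < length(z) && z[j] > z[j - 1] && z[j] >= z[j + 1]) {
        left <- min(z[max(which(z[1:(j - 1)] > z[j]), 1):j])
        if (!any(z[1:(j - 1)] > z[j])) left <- min(z[1:j])
        rest <- z[(j + 1):length(z)]
        hi <- which(rest > z[j])
        right <- if (length(hi)) min(z[j:(j + hi[1] - 1)]) else min(z[j:length(z)])
        if (z[j] - max(left, right) >= 0.5) best <- max(best, z[j])
      }
    }
    if (is.finite(best)) {
      expect_false(bp$fallback)
      expect_equal(bp$amplitude, best)
    } else {
      expect_true(bp$fallback)
      expect_equal(bp$amplitude, max(z[idx]))
    }
  }
})

test_that("event alignment stacks snippets, drops uncovered events, and appends mean/SEM", {
  tr <- make_trace(z = rep(2, 1000))
  al <- align_to_events(tr, events = 5, pre = 1, post = 1)
  expect_identical(nrow(al$values), 1L)
  expect_true(all(al$values == 2))
  expect_true(all(al$sem == 0))
  # identical transients at three events
  fs <- 100
  t <- (0:2999) / fs
  z <- test_kernel(t - 5) + test_kernel(t - 15) + test_kernel(t - 25)
  # rows differ only through the ~1e-5 tails of earlier kernels
  al3 <- align_to_events(make_trace(z = z), c(5, 15, 25), pre = 2, post = 4)
  expect_equal(al3$mean, al3$values[1, ], tolerance = 1e-4)
  expect_lt(max(al3$sem), 1e-4)
  # events too close to the edges are dropped, not padded
  al_drop <- align_to_events(make_trace(z = z), c(0.5, 15, 29.8), pre = 2,
                             post = 4)
  expect_identical(nrow(al_drop$values), 1L)
  expect_equal(al_drop$dropped, c(0.5, 29.8))
  expect_error(align_to_events(make_trace(z = z), c(0.1), pre = 2, post = 4),
               "coverage")
  # mean/SEM rows equal independent column statistics
  set.seed(10)
  zr <- rnorm(3000)
  alr <- align_to_events(make_trace(z = zr), c(4, 11, 17, 23), pre = 1, post = 2)
  expect_equal(alr$mean, colMeans(alr$values))
  expect_equal(alr$sem, apply(alr$values, 2, sd) / 2)
})

test_that("event-aligned pure-noise means shrink like one over root n", {
  # max |mean| across the window, compared with 3x the Gaussian envelope
  fs <- 50
  for (n in c(4, 16, 64)) {
    set.seed(n)
    z <- rnorm(fs * (6 * n + 20))
    events <- 5 + (0:(n - 1)) * 6
    al <- align_to_events(make_trace(z = z, fs = fs), events, pre = 1, post = 1)
    bound <- 3 * sqrt(2 * log(length(al$mean))) / sqrt(n)
    expect_lt(max(abs(al$mean)), bound)
  }
})

test_that("stimulus responses isolate a disk-1-only transient (habituation pattern)", {
  # a transient that has decayed back near baseline by the next disk onset
  fs <- 100
  t <- (0:3999) / fs
  trig <- 20
  set.seed(12)
  z <- 3 * test_kernel(t - (trig + 0.35), decay = 0.2) + rnorm(4000, 0, 0.05)
  tr <- make_trace(z = z)
  train <- loom_schedule(loom_params(), trig)
  resp <- stimulus_response(tr, train)
  expect_equal(resp$disks$onset, train$disk_onsets)  # schedule passthrough
  expect_gt(resp$disks$amplitude[1], 2.5)
  expect_true(all(resp$disks$amplitude[2:5] < 1))
  expect_gt(resp$disks$amplitude[1], 3 * max(resp$disks$amplitude[2:5]))
  expect_error(stimulus_response(make_trace(z = rnorm(300)), train), "past")
})
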