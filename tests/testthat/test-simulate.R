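test_that("noise-free construction reproduces the transient kernel exactly", {
  p <- photometry_sim_params(artifact_sd = 0, white_noise_sd = 0,
                             bleach_amplitude_465 = 0,
                             bleach_amplitude_405 = 0,
                             duration = 20,
                             transient_times = 10, transient_amplitudes = 2,
                             seed = 1)
  sim <- simulate_photometry(p)
  t <- sim$recording$time
  expect_equal(sim$recording$f465 - p$baseline_465, 2 * test_kernel(t - 10),
               tolerance = 1e-12)
  expect_equal(sim$recording$f405, rep(p$baseline_405, length(t)))
  expect_equal(max(sim$recording$f465) - p$baseline_465, 2, tolerance = 0.01)
})

test_that("both channels carry the identical artifact realization", {
  p <- photometry_sim_params(artifact_sd = 1.3, white_noise_sd = 0,
                             duration = 30, seed = 2)
  sim <- simulate_photometry(p)
  t <- sim$recording$time
  a465 <- sim$recording$f465 - p$baseline_465 -
    p$bleach_amplitude_465 * exp(-t / p$bleach_tau_465)
  a405 <- sim$recording$f405 - p$baseline_405 -
    p$bleach_amplitude_405 * exp(-t / p$bleach_tau_405)
  expect_equal(a465, a405, tolerance = 1e-12)
})

test_that("the channel contract approaches perfect correlation as white noise vanishes", {
  cors <- sapply(c(0.5, 0.05, 0.001), function(w) {
    p <- photometry_sim_params(white_noise_sd = w, duration = 30, seed = 5)
    sim <- simulate_photometry(p)
    t <- sim$recording$time
    tru <- numeric(length(t))
    for (i in seq_along(p$transient_times))
      tru <- tru + p$transient_amplitudes[i] * test_kernel(t - p$transient_times[i])
    cor(sim$recording$f465 - tru -
          p$bleach_amplitude_465 * exp(-t / p$bleach_tau_465),
        sim$recording$f405 -
          p$bleach_amplitude_405 * exp(-t / p$bleach_tau_405))
  })
  expect_true(all(diff(cors) > 0))
  expect_gt(cors[3], 0.9999)
})

test_that("simulation is bitwise reproducible and ground truth is complete", {
  tt <- c(1, 3, 5, 7, 9)
  p <- photometry_sim_params(duration = 12, transient_times = tt,
                             transient_amplitudes = seq(0.5, 2.5, by = 0.5),
                             seed = 77)
  s1 <- simulate_photometry(p)
  s2 <- simulate_photometry(p)
  expect_identical(s1$recording$f465, s2$recording$f465)
  expect_identical(s1$recording$f405, s2$recording$f405)
  expect_identical(s1$truth$transient_times, tt)
  expect_length(s1$truth$transient_amplitudes, 5L)
  # full-session determinism
  a <- simulate_session(behav = fast_behav(), seed = 9)
  b <- simulate_session(behav = fast_behav(), seed = 9)
  expect_identical(a$recording$f465, b$recording$f465)
  expect_identical(a$track$x, b$track$x)
  expect_identical(a$truth$stimulus_amplitude_z, b$truth$stimulus_amplitude_z)
})

test_that("invalid photometry parameters are rejected", {
  expect_error(photometry_sim_params(transient_times = 15,
                                     transient_amplitudes = 1,
                                     duration = 10), "within")
  expect_error(photometry_sim_params(transient_times = 5,
                                     transient_amplitudes = -1), ">= 0")
  expect_error(photometry_sim_params(baseline_465 = NaN), "non-finite")
  expect_error(photometry_sim_params(rise_tau = 0), "rise_tau")
})

test_that("deterministic coupling orders latency against amplitude exactly", {
  cp <- coupling_params(latency_resid = 0, velocity_resid = 0,
                        acceleration_resid = 0, amplitude_sd = 0)
  # two sessions whose only difference is the programmed amplitude mean
  lat <- sapply(c(2, 4), function(a) {
    cpa <- cp; cpa$amplitude_mean <- a
    s <- simulate_session(behav = fast_behav(), coupling = cpa, seed = 21)
    s$truth$escape$latency
  })
  # larger amplitude, shorter latency, on the programmed line up to grid snap
  expect_lt(lat[2], lat[1])
  expect_equal(lat[1] - lat[2], 0.8 * 2, tolerance = 1 / 30 * 2)
})

test_that("negative programmed latencies are clipped and flagged", {
  cp <- coupling_params(latency_intercept = 0.1, latency_resid = 0)
  s <- simulate_session(behav = fast_behav(), coupling = cp, seed = 22)
  expect_true(s$truth$escape$latency_clipped)
  expect_gte(s$truth$escape$latency, 0.5 - 1e-9)
})

test_that("generated positions respect the arena and the speed bound", {
  geom <- arena_geometry()
  for (seed in 1:8) {
    s <- simulate_session(behav = fast_behav(), seed = 400 + seed)
    expect_true(all(s$track$x >= -0.5 & s$track$x <= geom$length + 0.5))
    expect_true(all(s$track$y >= -0.5 & s$track$y <= geom$width + 0.5))
    kin <- compute_kinematics(s$track, smooth_window = 0)
    vmax <- if (is.null(s$truth$escape)) 2 * 56 else
      2 * s$truth$escape$peak_velocity
    expect_lt(max(kin$speed[2:(length(kin$speed) - 1)]), vmax)
    # every programmed event lies within the session
    expect_lt(s$truth$trigger_time, max(s$track$time))
    if (!is.null(s$truth$escape))
      expect_lt(s$truth$escape$shelter_entry, max(s$track$time))
  }
})

test_that("the pre-stimulus trajectory contains a vigorous spontaneous bout", {
  s <- simulate_session(seed = 55)
  kin <- compute_kinematics(s$track)
  bouts <- detect_movement_bouts(kin, c(0, s$truth$trigger_time))
  expect_gte(nrow(bouts), 1L)
  expect_lt(min(abs(bouts$peak_time - s$truth$movement_bout$time)), 1)
})

test_that("the full pipeline recovers the programmed trigger within one sample", {
  for (seed in c(3, 14, 29)) {
    s <- simulate_session(behav = fast_behav(), seed = seed)
    res <- run_simulated_session(s, fast_config())
    expect_lte(abs(res$trigger_time - s$truth$trigger_time), 1 / 30 + 1e-9)
    expect_lte(abs(detect_trigger(s$track, exploration_min = 20) -
                     s$truth$trigger_time), 1 / 30 + 1e-9)
  }
})

test_that("cohorts derive per-mouse seeds deterministically and honour programmed escapers", {
  co1 <- simulate_cohort(4, behav = fast_behav(), seed = 101)
  co2 <- simulate_cohort(4, behav = fast_behav(), seed = 101)
  expect_identical(co1$truth$mouse_seeds, co2$truth$mouse_seeds)
  expect_identical(co1$sessions[[3]]$recording$f465,
                   co2$sessions[[3]]$recording$f465)
  expect_error(simulate_cohort(1), "at least 2")
  # 16 mice, 5 programmed non-escapers -> exactly 11 classified escapers
  co <- simulate_cohort(16, behav = fast_behav(), n_nonescapers = 5,
                        seed = 202)
  esc <- vapply(co$sessions, function(s) {
    kin <- compute_kinematics(s$track)
    classify_escaper(detect_escape(kin, s$track, s$train))
  }, logical(1))
  expect_identical(sum(esc), 11L)
  expect_identical(esc, co$truth$escaper)
})

test_that("null coupling produces amplitude-latency correlations from the theoretical null", {
  # With all slopes zero the programmed latency is independent of the
  # transient amplitude, so |r| over n = 11 mice exceeds 0.6 with
  # probability 2*pt(-2.25, 9) = 0.0512. Check the Monte-Carlo proportion
  # against that exact value within a 3-sigma binomial band.
  cp <- coupling_params(latency_slope = 0, velocity_slope = 0,
                        acceleration_slope = 0)
  n_seeds <- 200
  exceed <- logical(n_seeds)
  for (k in seq_len(n_seeds)) {
    co <- simulate_cohort(11, behav = fast_behav(),
                          phot = photometry_sim_params(),
                          coupling = cp, seed = 7000 + k)
    amp <- vapply(co$sessions, function(s) s$truth$stimulus_amplitude_z,
                  numeric(1))
    lat <- vapply(co$sessions, function(s) s$truth$escape$latency, numeric(1))
    exceed[k] <- abs(cor(amp, lat)) >= 0.6
  }
  p0 <- 2 * stats::pt(-0.6 * 3 / sqrt(1 - 0.36), 9)
  band <- 3 * sqrt(p0 * (1 - p0) / n_seeds)
  expect_lt(mean(exceed), p0 + band)
  expect_gt(mean(!exceed), 0.9)
})

test_that("cohort ground truth records the programmed regression", {
  co <- simulate_cohort(3, behav = fast_behav(), seed = 77)
  expect_equal(co$truth$population_r2[["latency"]],
               0.8^2 * 1.5^2 / (0.8^2 * 1.5^2 + 0.6^2))
  expect_equal(co$truth$population_r2[["latency"]], 0.8)
  expect_s3_class(co$truth$coupling, "coupling_params")
})
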