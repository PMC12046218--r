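test_that("kinematics of scripted motion match the analytic derivatives", {
  fs <- 30
  t <- (0:299) / fs
  kin <- make_kin(10 * t + 5, fs = fs,
                  geometry = arena_geometry(length = 120))
  expect_equal(kin$speed, rep(10, 300), tolerance = 1e-9)
  expect_equal(kin$acceleration[2:299], rep(0, 298), tolerance = 1e-6)
  # static mouse
  kin0 <- make_kin(rep(30, 100), fs = fs)
  expect_equal(kin0$speed, rep(0, 100))
  # sinusoidal path at 100 Hz: speed tracks |cos| on interior samples
  fs2 <- 100
  t2 <- (0:999) / fs2
  x <- 30 + 5 * sin(t2)
  tr <- tracking_trace(t2, x, rep(10, 1000))
  kin2 <- compute_kinematics(tr, smooth_window = 0)
  interior <- 2:999
  expect_equal(kin2$speed[interior], 5 * abs(cos(t2[interior])),
               tolerance = 0.01)
})

test_that("kinematics scale linearly with position scaling", {
  set.seed(20)
  x <- 30 + cumsum(rnorm(200, 0, 0.1))
  y <- 10 + cumsum(rnorm(200, 0, 0.1))
  k1 <- make_kin(x, y)
  k2 <- make_kin(0.5 * (x - 30) + 30, 0.5 * (y - 10) + 10)
  # offset-recentred half-scale trajectory halves speed and acceleration
  expect_equal(k2$speed, 0.5 * k1$speed, tolerance = 1e-9)
  expect_equal(k2$acceleration, 0.5 * k1$acceleration, tolerance = 1e-9)
})

test_that("non-uniform sampling is rejected", {
  t <- c(0, 0.1, 0.2, 0.35, 0.4, 0.5)
  tr <- tracking_trace(t, rep(10, 6), rep(10, 6))
  expect_error(compute_kinematics(tr), "non-uniform")
})

test_that("trigger fires at the first threat-zone sample after exploration", {
  fs <- 30
  n <- round(320 * fs)
  t <- (0:(n - 1)) / fs
  x <- rep(40, n)
  x[t >= 312.4] <- 10  # scripted entry
  tr <- tracking_trace(t, x, rep(10, n))
  expect_lt(abs(detect_trigger(tr) - 312.4), 1 / fs + 1e-9)
  # already inside the zone when exploration ends
  tr2 <- tracking_trace(t, rep(10, n), rep(10, n))
  expect_equal(detect_trigger(tr2), 300, tolerance = 1 / fs)
  # never enters
  tr3 <- tracking_trace(t, rep(40, n), rep(10, n))
  expect_error(detect_trigger(tr3), "never enters")
  expect_error(detect_trigger(tracking_trace(t[1:100], rep(40, 100),
                                             rep(10, 100))), "shorter")
})

test_that("programmed escapes are recovered within tight tolerances", {
  s <- simulate_session(behav = fast_behav(escape_latency = 3,
                                           escape_peak_velocity = 55,
                                           escape_peak_acceleration = 360),
                        coupling = NULL, seed = 31)
  kin <- compute_kinematics(s$track)
  esc <- detect_escape(kin, s$track, s$train)
  expect_s3_class(esc, "escape_bout")
  expect_lt(abs(esc$latency - s$truth$escape$latency), 0.2)
  expect_lt(abs(esc$peak_velocity - 55) / 55, 0.05)
  expect_lte(esc$onset, esc$shelter_entry)
  expect_gt(esc$latency, 0)
  expect_lte(esc$shelter_entry - s$train$disk_onsets[1], 10)
})

test_that("non-escape sessions yield no bout and invalid trials are flagged", {
  s <- simulate_session(behav = fast_behav(escapes = FALSE), seed = 32)
  kin <- compute_kinematics(s$track)
  expect_null(detect_escape(kin, s$track, s$train))
  expect_null(s$truth$escape)
  geom <- arena_geometry()
  expect_false(any(in_shelter(s$track$x[s$track$time > s$truth$trigger_time],
                              s$track$y[s$track$time > s$truth$trigger_time],
                              geom)))
  # mouse already sheltering at disk onset -> invalid trial
  fs <- 30
  n <- 31 * fs
  t <- (0:(n - 1)) / fs
  tr <- tracking_trace(t, rep(58, n), rep(10, n))
  kin2 <- compute_kinematics(tr)
  train <- loom_schedule(loom_params(), 15)
  expect_warning(res <- detect_escape(kin2, tr, train), "invalid trial")
  expect_null(res)
})

test_that("movement bouts are segmented, merged across short gaps, and vigor-filtered", {
  fs <- 30
  t <- (0:599) / fs
  sp <- rep(0, 600)
  sp[t >= 3 & t <= 4.2] <- 30 * sin(pi * (t[t >= 3 & t <= 4.2] - 3) / 1.2)^2
  # integrate scripted speed into a position trace
  x <- 5 + cumsum(sp) / fs
  kin <- make_kin(x, fs = fs)
  bouts <- detect_movement_bouts(kin, c(0, 20))
  expect_identical(nrow(bouts), 1L)
  expect_lt(abs(bouts$peak_velocity - 30) / 30, 0.05)
  # speed identically zero
  expect_identical(nrow(detect_movement_bouts(make_kin(rep(10, 300)),
                                              c(0, 9))), 0L)
  # two supra-floor episodes separated by 0.3 s merge into one bout
  sp2 <- rep(0, 600)
  sp2[t >= 2 & t <= 3] <- 25
  sp2[t >= 3.3 & t <= 4.3] <- 25
  x2 <- 5 + cumsum(sp2) / fs
  kin2 <- make_kin(x2, fs = fs, geometry = arena_geometry(length = 80))
  bouts2 <- detect_movement_bouts(kin2, c(0, 20), merge_gap = 0.5)
  expect_identical(nrow(bouts2), 1L)
})

test_that("freezing requires sustained immobility outside the shelter", {
  fs <- 30
  t <- (0:299) / fs
  sp <- rep(5, 300)
  sp[t >= 3 & t <= 5] <- 0  # 2-s immobility
  x <- 5 + cumsum(sp) / fs
  kin <- make_kin(x, fs = fs, geometry = arena_geometry(length = 80))
  fr <- detect_freezing(kin, c(0, 9.9))
  expect_identical(nrow(fr), 1L)
  expect_lt(abs((fr$end - fr$start) - 2), 0.3)
  # continuous locomotion freezes nowhere
  expect_identical(nrow(detect_freezing(make_kin(5 + 5 * (0:299) / fs,
                                                 fs = fs,
                                                 geometry = arena_geometry(length = 80)),
                                        c(0, 9.9))), 0L)
  # immobility inside the shelter is sheltering, not freezing
  kin_sh <- make_kin(rep(57, 300), fs = fs)
  expect_identical(nrow(detect_freezing(kin_sh, c(0, 9.9))), 0L)
})

test_that("escaper classification reflects bout presence", {
  s <- simulate_session(behav = fast_behav(), coupling = NULL, seed = 33)
  kin <- compute_kinematics(s$track)
  expect_true(classify_escaper(detect_escape(kin, s$track, s$train)))
  expect_false(classify_escaper(NULL))
})

test_that("segmentation is stable when the same trajectory is sampled at 30 and 60 Hz", {
  # analytic trajectory: rest, then a raised-cosine dash into the shelter
  make_track <- function(fs) {
    t <- seq(0, 30, by = 1 / fs)
    onset <- 16; Tt <- 1.2; vp <- 50
    disp <- ifelse(t < onset, 0,
                   ifelse(t < onset + Tt,
                          vp * ((t - onset) / 2 -
                                  Tt / (4 * pi) * sin(2 * pi * (t - onset) / Tt)),
                          vp * Tt / 2))
    tracking_trace(t, 20 + disp, rep(10, length(t)))
  }
  tr30 <- make_track(30); tr60 <- make_track(60)
  train <- loom_schedule(loom_params(), 15)
  e30 <- detect_escape(compute_kinematics(tr30), tr30, train)
  e60 <- detect_escape(compute_kinematics(tr60), tr60, train)
  expect_lte(abs(e30$onset - e60$onset), 1 / 30 + 1e-9)
  expect_lte(abs(e30$shelter_entry - e60$shelter_entry), 1 / 30 + 1e-9)
})

test_that("arena geometry validates zones and positions", {
  expect_error(arena_geometry(length = 30, threat_zone_size = 20,
                              shelter_depth = 12), "length")
  g <- arena_geometry()
  expect_error(tracking_trace(c(0, 1), c(-5, 10), c(10, 10), g), "outside")
  expect_error(tracking_trace(c(0, 0), c(10, 10), c(10, 10), g),
               "strictly increasing")
  expect_true(in_threat_zone(5, 5, g))
  expect_false(in_threat_zone(25, 5, g))
  expect_true(in_shelter(55, 10, g))
})
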