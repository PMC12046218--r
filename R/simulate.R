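# Synthetic photometry + behavior sessions with full ground truth.
#
# The generator emulates the statistical structure the analysis assumes:
# a 465 nm signal channel = baseline + exponential photobleaching + a
# low-pass motion-artifact process (shared with the reference channel) +
# a train of sensor transients + white noise; a 405 nm reference channel
# with the identical artifact realization and no transients; mouse
# trajectories in the rectangular shelter/threat-zone arena with a
# threat-zone-triggered looming train, an arrest-then-flight escape bout,
# and a programmable linear coupling between the stimulus-evoked transient
# amplitude and the escape kinematics.

#' Photometry simulation parameters
#'
#' @param sampling_rate Hz.
#' @param duration seconds.
#' @param baseline_465,baseline_405 static fluorescence level per channel
#'   (a.u.).
#' @param bleach_amplitude_465,bleach_amplitude_405 initial amplitude of the
#'   exponential photobleaching decay per channel (a.u.).
#' @param bleach_tau_465,bleach_tau_405 bleaching time constants, seconds.
#' @param artifact_sd stationary standard deviation of the shared low-pass
#'   motion-artifact process (a.u.). Motion artifacts dominate white
#'   measurement noise by several-fold in freely moving recordings, hence
#'   the default.
#' @param artifact_tau correlation time of the artifact process, seconds.
#' @param rise_tau,decay_tau transient kernel time constants, seconds
#'   (difference of exponentials normalized to unit peak; sub-second
#'   kinetics typical of dopamine-sensor transients).
#' @param transient_times transient onset times, seconds, within
#'   `[0, duration)`.
#' @param transient_amplitudes transient peak amplitudes (a.u., >= 0), one
#'   per time.
#' @param white_noise_sd per-channel white measurement noise sd (a.u.).
#' @param zunit_scale a.u. per z unit: the conversion the session generator
#'   uses to inject transients whose post-correction z-scored amplitude is
#'   approximately the programmed z value (matched to the default noise
#'   floor of the corrected trace).
#' @param seed optional RNG seed.
#' @return An object of class `photometry_sim_params`.
#' @export
photometry_sim_params <- function(sampling_rate = 100, duration = 10,
                                  baseline_465 = 100, baseline_405 = 80,
                                  bleach_amplitude_465 = 5,
                                  bleach_amplitude_405 = 4,
                                  bleach_tau_465 = 600, bleach_tau_405 = 600,
                                  artifact_sd = 1.0, artifact_tau = 0.5,
                                  rise_tau = 0.1, decay_tau = 0.8,
                                  transient_times = numeric(),
                                  transient_amplitudes = numeric(),
                                  white_noise_sd = 0.2,
                                  zunit_scale = 0.28, seed = NULL) {
  p <- list(sampling_rate = sampling_rate, duration = duration,
            baseline_465 = baseline_465, baseline_405 = baseline_405,
            bleach_amplitude_465 = bleach_amplitude_465,
            bleach_amplitude_405 = bleach_amplitude_405,
            bleach_tau_465 = bleach_tau_465, bleach_tau_405 = bleach_tau_405,
            artifact_sd = artifact_sd, artifact_tau = artifact_tau,
            rise_tau = rise_tau, decay_tau = decay_tau,
            transient_times = as.numeric(transient_times),
            transient_amplitudes = as.numeric(transient_amplitudes),
            white_noise_sd = white_noise_sd, zunit_scale = zunit_scale,
            seed = seed)
  num <- unlist(p[setdiff(names(p), c("seed", "transient_times",
                                      "transient_amplitudes"))])
  if (!all(is.finite(num))) stop("non-finite photometry parameter")
  stopifnot(sampling_rate > 0, duration > 0, bleach_tau_465 > 0,
            bleach_tau_405 > 0, artifact_tau > 0, rise_tau > 0,
            decay_tau > 0, rise_tau < decay_tau, artifact_sd >= 0,
            white_noise_sd >= 0, zunit_scale > 0,
            length(p$transient_times) == length(p$transient_amplitudes))
  if (length(p$transient_times)) {
    if (!all(is.finite(p$transient_times)) ||
        !all(is.finite(p$transient_amplitudes)))
      stop("non-finite transient specification")
    if (any(p$transient_times < 0 | p$transient_times >= duration))
      stop("transient times must lie within [0, duration)")
    if (any(p$transient_amplitudes < 0))
      stop("transient amplitudes must be >= 0")
  }
  structure(p, class = "photometry_sim_params")
}

#' Behavior simulation parameters
#'
#' @param geometry an [arena_geometry()].
#' @param tracking_rate Hz.
#' @param exploration_speed_scale typical exploration speed (cm/s) of the
#'   reflected Ornstein-Uhlenbeck velocity process.
#' @param exploration_min free-exploration period before the trigger can
#'   fire, seconds (5 min by default).
#' @param trigger_delay `(min, max)` seconds after `exploration_min` at
#'   which the scripted threat-zone approach delivers the mouse to the
#'   zone; the realized trigger is the first in-zone tracking sample.
#' @param approach_duration duration of the scripted approach, seconds.
#' @param post_duration recording time after the trigger, seconds.
#' @param movement_bout_peak peak speed of the scripted vigorous
#'   exploration bout, cm/s.
#' @param movement_bout_duration duration of that bout, seconds.
#' @param escapes logical: does this mouse flee to shelter?
#' @param escape_latency,escape_peak_velocity,escape_peak_acceleration
#'   programmed escape kinematics used when no coupling model is supplied
#'   (seconds, cm/s, cm/s^2). Defaults follow the cohort means typical of
#'   this assay.
#' @param stimulus_amplitude_z stimulus-evoked transient amplitude (z
#'   units) used when no coupling model is supplied.
#' @param escape_transient_z amplitude of an additional transient injected
#'   shortly after escape onset (z units; 0 disables).
#' @param seed optional RNG seed.
#' @return An object of class `behavior_sim_params`.
#' @export
behavior_sim_params <- function(geometry = arena_geometry(),
                                tracking_rate = 30,
                                exploration_speed_scale = 6,
                                exploration_min = 300,
                                trigger_delay = c(5, 20),
                                approach_duration = 3,
                                post_duration = 180,
                                movement_bout_peak = 30,
                                movement_bout_duration = 1.2,
                                escapes = TRUE,
                                escape_latency = 3.8,
                                escape_peak_velocity = 56,
                                escape_peak_acceleration = 360,
                                stimulus_amplitude_z = 3,
                                escape_transient_z = 0,
                                seed = NULL) {
  stopifnot(inherits(geometry, "arena_geometry"), tracking_rate > 0,
            exploration_speed_scale > 0, exploration_min >= 0,
            length(trigger_delay) == 2L, trigger_delay[1L] > 0,
            trigger_delay[2L] >= trigger_delay[1L],
            approach_duration > 0,
            trigger_delay[1L] > approach_duration,
            post_duration > 0, movement_bout_peak >= 0,
            movement_bout_duration > 0, is.logical(escapes),
            escape_peak_velocity > 0, escape_peak_acceleration > 0,
            stimulus_amplitude_z >= 0, escape_transient_z >= 0)
  if (escapes && escape_latency <= 0)
    stop("escape_latency must be > 0 when escapes = TRUE")
  structure(list(geometry = geometry, tracking_rate = tracking_rate,
                 exploration_speed_scale = exploration_speed_scale,
                 exploration_min = exploration_min,
                 trigger_delay = trigger_delay,
                 approach_duration = approach_duration,
                 post_duration = post_duration,
                 movement_bout_peak = movement_bout_peak,
                 movement_bout_duration = movement_bout_duration,
                 escapes = escapes, escape_latency = escape_latency,
                 escape_peak_velocity = escape_peak_velocity,
                 escape_peak_acceleration = escape_peak_acceleration,
                 stimulus_amplitude_z = stimulus_amplitude_z,
                 escape_transient_z = escape_transient_z, seed = seed),
            class = "behavior_sim_params")
}

#' Amplitude-to-kinematics coupling parameters
#'
#' Linear model linking the stimulus-evoked transient amplitude (z units)
#' to the programmed escape kinematics:
#' `metric = intercept + slope * amplitude + N(0, resid)`. The defaults
#' give population coefficients of determination of 0.8 (latency) and
#' about 0.72 (peak velocity and peak acceleration) around cohort means of
#' roughly 3.8 s, 56 cm/s and 364 cm/s^2, with amplitudes of 3 +/- 1.5 z
#' (the between-animal spread implied by the assay's printed cohort
#' statistics).
#'
#' @param latency_slope s per z unit (negative: larger transients, faster
#'   escapes).
#' @param latency_intercept,latency_resid seconds.
#' @param velocity_slope cm/s per z unit.
#' @param velocity_intercept,velocity_resid cm/s.
#' @param acceleration_slope cm/s^2 per z unit.
#' @param acceleration_intercept,acceleration_resid cm/s^2.
#' @param amplitude_mean,amplitude_sd z units.
#' @return An object of class `coupling_params`. The population R^2 per
#'   metric is available from [coupling_r2()].
#' @export
coupling_params <- function(latency_slope = -0.8, latency_intercept = 6.2,
                            latency_resid = 0.6,
                            velocity_slope = 8, velocity_intercept = 32.3,
                            velocity_resid = 7.5,
                            acceleration_slope = 80,
                            acceleration_intercept = 123.5,
                            acceleration_resid = 75,
                            amplitude_mean = 3, amplitude_sd = 1.5) {
  stopifnot(latency_resid >= 0, velocity_resid >= 0,
            acceleration_resid >= 0, amplitude_sd >= 0)
  structure(list(latency_slope = latency_slope,
                 latency_intercept = latency_intercept,
                 latency_resid = latency_resid,
                 velocity_slope = velocity_slope,
                 velocity_intercept = velocity_intercept,
                 velocity_resid = velocity_resid,
                 acceleration_slope = acceleration_slope,
                 acceleration_intercept = acceleration_intercept,
                 acceleration_resid = acceleration_resid,
                 amplitude_mean = amplitude_mean,
                 amplitude_sd = amplitude_sd),
            class = "coupling_params")
}

#' Population R-squared implied by a coupling model
#'
#' `slope^2 * amplitude_sd^2 / (slope^2 * amplitude_sd^2 + resid^2)` for
#' the requested metric.
#'
#' @param coupling a [coupling_params()] object.
#' @param metric `"latency"`, `"velocity"` or `"acceleration"`.
#' @return Population coefficient of determination in `[0, 1]`.
#' @export
coupling_r2 <- function(coupling, metric = c("latency", "velocity",
                                             "acceleration")) {
  metric <- match.arg(metric)
  stopifnot(inherits(coupling, "coupling_params"))
  sl <- coupling[[paste0(metric, "_slope")]]
  rs <- coupling[[paste0(metric, "_resid")]]
  sig <- sl^2 * coupling$amplitude_sd^2
  if (sig == 0 && rs == 0) return(NA_real_)
  sig / (sig + rs^2)
}

# Unit-peak difference-of-exponentials transient kernel.
.transient_kernel <- function(t, rise, decay) {
  tpk <- rise * decay / (decay - rise) * log(decay / rise)
  peak <- exp(-tpk / decay) - exp(-tpk / rise)
  out <- numeric(length(t))
  pos <- t >= 0
  out[pos] <- (exp(-t[pos] / decay) - exp(-t[pos] / rise)) / peak
  out
}

# Stationary AR(1) realization of an Ornstein-Uhlenbeck process.
.ou_series <- function(n, sd, tau, dt) {
  phi <- exp(-dt / tau)
  innov <- stats::rnorm(n) * sd * sqrt(1 - phi^2)
  innov[1L] <- stats::rnorm(1) * sd
  as.numeric(stats::filter(innov, phi, method = "recursive"))
}

#' Simulate a two-channel photometry recording
#'
#' Both channels share the identical motion-artifact realization and
#' bleaching structure; transients are added to the signal channel only.
#' Bitwise reproducible for a fixed seed.
#'
#' @param params a [photometry_sim_params()] object.
#' @return A list with `recording` (a [photometry_recording()]) and
#'   `truth` (a `session_ground_truth` list: injected transient
#'   times/amplitudes, bleaching parameters, artifact summary, seed).
#' @export
simulate_photometry <- function(params = photometry_sim_params()) {
  stopifnot(inherits(params, "photometry_sim_params"))
  if (!is.null(params$seed)) set.seed(params$seed)
  fs <- params$sampling_rate
  n <- max(2L, round(params$duration * fs))
  t <- (seq_len(n) - 1L) / fs
  bleach465 <- params$bleach_amplitude_465 * exp(-t / params$bleach_tau_465)
  bleach405 <- params$bleach_amplitude_405 * exp(-t / params$bleach_tau_405)
  artifact <- .ou_series(n, 1, params$artifact_tau, 1 / fs) * params$artifact_sd
  transients <- numeric(n)
  for (i in seq_along(params$transient_times)) {
    ti <- params$transient_times[i]
    i0 <- floor(ti * fs) + 1L
    idx <- i0:n
    transients[idx] <- transients[idx] +
      params$transient_amplitudes[i] *
      .transient_kernel(t[idx] - ti, params$rise_tau, params$decay_tau)
  }
  w465 <- stats::rnorm(n) * params$white_noise_sd
  w405 <- stats::rnorm(n) * params$white_noise_sd
  f465 <- params$baseline_465 + bleach465 + artifact + transients + w465
  f405 <- params$baseline_405 + bleach405 + artifact + w405
  rec <- photometry_recording(t, f465, f405, fs)
  truth <- structure(list(
    transient_times = params$transient_times,
    transient_amplitudes = params$transient_amplitudes,
    bleach = list(amplitude_465 = params$bleach_amplitude_465,
                  amplitude_405 = params$bleach_amplitude_405,
                  tau_465 = params$bleach_tau_465,
                  tau_405 = params$bleach_tau_405),
    artifact = list(sd = params$artifact_sd, tau = params$artifact_tau,
                    realized_sd = stats::sd(artifact)),
    white_noise_sd = params$white_noise_sd,
    seed = params$seed), class = "session_ground_truth")
  list(recording = rec, truth = truth)
}

# Raised-cosine ramp-up / cruise / ramp-down speed profile covering
# `distance` cm with peak `vpeak`; the ramp-up duration is chosen so its
# acceleration peaks at `apeak`. When the requested ramp would not fit
# the distance the ramp is capped (realized acceleration recomputed
# analytically and flagged); the deceleration phase absorbs whatever
# distance remains after a cruise of at least `min_cruise` seconds, so
# the programmed peak velocity is always held long enough to survive
# position smoothing.
.escape_profile <- function(distance, vpeak, apeak, min_cruise = 0.25) {
  tr <- pi * vpeak / (2 * apeak)
  d_up <- vpeak * tr / 2
  capped <- FALSE
  if (d_up > 0.45 * distance) {
    d_up <- 0.45 * distance
    tr <- 2 * d_up / vpeak
    capped <- TRUE
  }
  rem <- distance - d_up
  d_dn <- min(d_up, max(0, rem - min_cruise * vpeak))
  td <- 2 * d_dn / vpeak
  tc <- (rem - d_dn) / vpeak
  list(type = if (capped) "acceleration_capped" else "plateau",
       t_up = tr, t_cruise = tc, t_down = td, total = tr + tc + td,
       vpeak = vpeak, apeak = pi * vpeak / (2 * tr))
}

.profile_speed <- function(prof, t) {
  v <- numeric(length(t))
  up <- t >= 0 & t < prof$t_up
  v[up] <- prof$vpeak * sin(pi * t[up] / (2 * prof$t_up))^2
  mid <- t >= prof$t_up & t < prof$t_up + prof$t_cruise
  v[mid] <- prof$vpeak
  if (prof$t_down > 0) {
    dn <- t >= prof$t_up + prof$t_cruise & t <= prof$total
    v[dn] <- prof$vpeak * sin(pi * (prof$total - t[dn]) / (2 * prof$t_down))^2
  }
  v
}

# Reflect a coordinate into [lo, hi], flipping the matching velocity sign.
.reflect1 <- function(p, v, lo, hi) {
  if (p < lo) { p <- 2 * lo - p; v <- -v }
  if (p > hi) { p <- 2 * hi - p; v <- -v }
  c(p, v)
}

#' Simulate a full looming-assay session
#'
#' Generates the tracking trajectory (reflected Ornstein-Uhlenbeck
#' exploration with one scripted vigorous movement bout, a scripted
#' threat-zone approach, stimulus-locked arrest, and - for escapers - a
#' raised-cosine flight to shelter), the looming train triggered at the
#' first in-zone sample after the exploration period, and a matched
#' photometry recording with a stimulus-evoked transient injected 0.3-0.6 s
#' after disk-1 onset. When a coupling model is supplied the transient
#' amplitude is drawn from it and the escape kinematics follow the
#' programmed linear relation (latencies below 0.5 s are clipped and
#' flagged); otherwise the fixed kinematics in `behav` are used.
#'
#' @param phot a [photometry_sim_params()] (its `duration`,
#'   `transient_times` and `transient_amplitudes` are overridden by the
#'   session script).
#' @param behav a [behavior_sim_params()].
#' @param coupling a [coupling_params()] or `NULL`.
#' @param loom a [loom_params()].
#' @param seed RNG seed for the whole session.
#' @return A list of class `simulated_session`: `recording`, `track`,
#'   `train`, `truth`.
#' @export
simulate_session <- function(phot = photometry_sim_params(),
                             behav = behavior_sim_params(),
                             coupling = coupling_params(),
                             loom = loom_params(), seed = NULL) {
  stopifnot(inherits(phot, "photometry_sim_params"),
            inherits(behav, "behavior_sim_params"),
            is.null(coupling) || inherits(coupling, "coupling_params"),
            inherits(loom, "loom_params"))
  if (!is.null(seed)) set.seed(seed)
  geom <- behav$geometry
  rate <- behav$tracking_rate
  dt <- 1 / rate

  # --- programmed stimulus transient and escape kinematics ----------------
  clipped <- FALSE
  if (!is.null(coupling)) {
    amp_z <- max(0, stats::rnorm(1, coupling$amplitude_mean,
                                 coupling$amplitude_sd))
    latency <- coupling$latency_intercept + coupling$latency_slope * amp_z +
      stats::rnorm(1, 0, coupling$latency_resid)
    vpeak <- coupling$velocity_intercept + coupling$velocity_slope * amp_z +
      stats::rnorm(1, 0, coupling$velocity_resid)
    apeak <- coupling$acceleration_intercept +
      coupling$acceleration_slope * amp_z +
      stats::rnorm(1, 0, coupling$acceleration_resid)
  } else {
    amp_z <- behav$stimulus_amplitude_z
    latency <- behav$escape_latency
    vpeak <- behav$escape_peak_velocity
    apeak <- behav$escape_peak_acceleration
  }
  if (latency < 0.5) { latency <- 0.5; clipped <- TRUE }
  vpeak <- max(vpeak, 25)
  apeak <- max(apeak, 60)

  # --- phase 1: exploration (reflected OU velocity process) --------------
  delay <- stats::runif(1, behav$trigger_delay[1L], behav$trigger_delay[2L])
  i_appr <- round((behav$exploration_min + delay - behav$approach_duration) *
                    rate) + 1L
  n_appr <- round(behav$approach_duration * rate)
  sigma_v <- behav$exploration_speed_scale / 1.25  # per-axis OU sd
  tau_v <- 0.7
  phi <- exp(-dt / tau_v)
  isd <- sigma_v * sqrt(1 - phi^2)
  n1 <- i_appr
  x <- numeric(n1); y <- numeric(n1)
  x[1L] <- geom$length / 2; y[1L] <- geom$width / 2
  vx <- stats::rnorm(1) * sigma_v; vy <- stats::rnorm(1) * sigma_v
  ex <- stats::rnorm(n1) * isd; ey <- stats::rnorm(n1) * isd
  # scripted vigorous bout inside the exploration period
  t_appr <- (i_appr - 1L) / rate
  hi <- min(240, t_appr - 5 - behav$movement_bout_duration)
  if (hi > 1) {
    bout_t0 <- stats::runif(1, min(60, hi / 2), hi)
  } else {
    bout_t0 <- NA_real_  # session too short for a scripted bout
  }
  ib0 <- if (is.na(bout_t0)) n1 + 1L else round(bout_t0 * rate) + 1L
  ib1 <- ib0 + round(behav$movement_bout_duration * rate)
  bout_dir <- 0
  for (i in 2:n1) {
    if (i == ib0) bout_dir <- if (x[i - 1L] < geom$length / 2) 1 else -1
    if (i >= ib0 && i <= ib1 && behav$movement_bout_peak > 0) {
      u <- (i - ib0) / (ib1 - ib0)
      sp <- behav$movement_bout_peak * sin(pi * u)^2
      vx <- bout_dir * sp; vy <- 0
    } else {
      vx <- phi * vx + ex[i]
      vy <- phi * vy + ey[i]
    }
    px <- x[i - 1L] + vx * dt; py <- y[i - 1L] + vy * dt
    rx <- .reflect1(px, vx, 0.3, geom$length - 0.3)
    ry <- .reflect1(py, vy, 0.3, geom$width - 0.3)
    x[i] <- rx[1L]; vx <- rx[2L]; y[i] <- ry[1L]; vy <- ry[2L]
  }

  # --- phase 2: scripted approach into the threat zone --------------------
  p0 <- c(x[n1], y[n1])
  target <- c(geom$threat_zone$xmax - 0.7,
              min(max(p0[2L], 3), geom$threat_zone$ymax - 3))
  u <- seq_len(n_appr) / n_appr
  s <- u^2 * (3 - 2 * u)  # smoothstep easing
  xa <- p0[1L] + s * (target[1L] - p0[1L])
  ya <- p0[2L] + s * (target[2L] - p0[2L])
  x <- c(x, xa); y <- c(y, ya)
  tgrid <- (seq_along(x) - 1L) * dt

  # realized trigger: first in-zone sample after the exploration period
  ok <- tgrid >= behav$exploration_min & in_threat_zone(x, y, geom)
  if (!any(ok)) stop("geometry violation: scripted approach missed the threat zone")
  i_trig <- which(ok)[1L]
  trigger_time <- tgrid[i_trig]
  train <- loom_schedule(loom, trigger_time)

  # --- phase 3: post-trigger script ---------------------------------------
  n_total <- i_trig + round(behav$post_duration * rate)
  x <- c(x[1:i_trig], numeric(n_total - i_trig))
  y <- c(y[1:i_trig], numeric(n_total - i_trig))
  jit <- function(m) stats::rnorm(m) * 0.03
  escape_truth <- NULL
  if (behav$escapes) {
    i_onset <- i_trig + round(latency * rate)
    # stimulus-locked arrest until movement onset
    narr <- i_onset - i_trig
    x[(i_trig + 1L):i_onset] <- x[i_trig] + jit(narr)
    y[(i_trig + 1L):i_onset] <- y[i_trig] + jit(narr)
    p_on <- c(x[i_onset], y[i_onset])
    goal <- c(geom$length - 2, min(max(p_on[2L], 2), geom$width - 2))
    dvec <- goal - p_on
    d_total <- sqrt(sum(dvec^2))
    udir <- dvec / d_total
    prof <- .escape_profile(d_total, vpeak, apeak)
    nb <- ceiling(prof$total * rate)
    tb <- seq_len(nb) * dt
    dist <- cumsum(.profile_speed(prof, tb - dt / 2)) * dt
    dist <- pmin(dist, d_total)
    seg <- i_onset + seq_len(nb)
    seg <- seg[seg <= n_total]
    x[seg] <- p_on[1L] + udir[1L] * dist[seq_along(seg)]
    y[seg] <- p_on[2L] + udir[2L] * dist[seq_along(seg)]
    i_end <- if (length(seg)) seg[length(seg)] else i_onset
    if (i_end < n_total) {
      m <- n_total - i_end
      x[(i_end + 1L):n_total] <- pmin(pmax(x[i_end] + jit(m),
                                           geom$shelter$xmin + 0.3),
                                      geom$length - 0.3)
      y[(i_end + 1L):n_total] <- pmin(pmax(y[i_end] + jit(m), 0.3),
                                      geom$width - 0.3)
    }
    ientry <- which(x > geom$shelter$xmin & seq_along(x) > i_trig)[1L]
    escape_truth <- list(onset = tgrid[1L] + (i_onset - 1L) * dt,
                         latency = (i_onset - i_trig) * dt,
                         peak_velocity = vpeak,
                         peak_acceleration = prof$apeak,
                         shelter_entry = (ientry - 1L) * dt,
                         profile = prof$type,
                         latency_clipped = clipped)
  } else {
    # brief arrest, then exploration that never reaches the shelter
    narr <- round(1.5 * rate)
    i_res <- min(i_trig + narr, n_total)
    x[(i_trig + 1L):i_res] <- x[i_trig] + jit(i_res - i_trig)
    y[(i_trig + 1L):i_res] <- y[i_trig] + jit(i_res - i_trig)
    vx <- 0; vy <- 0
    if (i_res < n_total) {
      m <- n_total - i_res
      ex <- stats::rnorm(m) * isd; ey <- stats::rnorm(m) * isd
      for (k in seq_len(m)) {
        i <- i_res + k
        vx <- phi * vx + ex[k]; vy <- phi * vy + ey[k]
        px <- x[i - 1L] + vx * dt; py <- y[i - 1L] + vy * dt
        rx <- .reflect1(px, vx, 0.3, geom$shelter$xmin - 1)
        ry <- .reflect1(py, vy, 0.3, geom$width - 0.3)
        x[i] <- rx[1L]; vx <- rx[2L]; y[i] <- ry[1L]; vy <- ry[2L]
      }
    }
  }
  tgrid <- (seq_len(n_total) - 1L) * dt
  track <- tracking_trace(tgrid, x, y, geom)

  # --- photometry with the scripted transient train -----------------------
  jitter <- stats::runif(1, 0.3, 0.6)
  tr_times <- trigger_time + jitter
  tr_amps_z <- amp_z
  if (behav$escapes && behav$escape_transient_z > 0) {
    tr_times <- c(tr_times, escape_truth$onset + 0.2)
    tr_amps_z <- c(tr_amps_z, behav$escape_transient_z)
  }
  duration <- tgrid[n_total] + 1 / phot$sampling_rate
  pp <- phot
  pp$duration <- duration
  pp$transient_times <- tr_times
  pp$transient_amplitudes <- tr_amps_z * phot$zunit_scale
  pp$seed <- NULL  # session RNG stream stays in control
  sim <- simulate_photometry(pp)
  sim$recording$events <- data.frame(
    label = c("trigger", sprintf("disk%d", seq_along(train$disk_onsets))),
    time_s = c(trigger_time, train$disk_onsets))

  truth <- sim$truth
  truth$trigger_time <- trigger_time
  truth$stimulus_amplitude_z <- amp_z
  truth$stimulus_transient_time <- trigger_time + jitter
  truth$escape <- escape_truth
  truth$movement_bout <- list(time = bout_t0 +
                                behav$movement_bout_duration / 2,
                              peak_velocity = behav$movement_bout_peak)
  truth$coupling <- coupling
  truth$seed <- seed
  structure(list(recording = sim$recording, track = track, train = train,
                 truth = truth),
            class = "simulated_session")
}

#' @export
print.simulated_session <- function(x, ...) {
  cat(sprintf("Simulated session: trigger %.2f s, stimulus amplitude %.2f z, %s\n",
              x$truth$trigger_time, x$truth$stimulus_amplitude_z,
              if (is.null(x$truth$escape)) "no escape"
              else sprintf("escape latency %.2f s", x$truth$escape$latency)))
  invisible(x)
}

#' Simulate a multi-animal cohort
#'
#' Per-mouse seeds are drawn deterministically from the master seed; the
#' cohort ground truth records the programmed amplitude-kinematics
#' regression (coupling coefficients and their population R^2) alongside
#' each session's truth.
#'
#' @param n_mice number of animals (>= 2).
#' @param phot,behav,coupling,loom session templates (see
#'   [simulate_session()]).
#' @param n_nonescapers how many mice are programmed not to flee (these
#'   take the last seeds).
#' @param seed master seed.
#' @return A list of class `simulated_cohort`: `sessions` (list of
#'   [simulate_session()] results) and `truth` (master seed, per-mouse
#'   seeds, escaper flags, coupling, population R^2 per metric).
#' @export
simulate_cohort <- function(n_mice, phot = photometry_sim_params(),
                            behav = behavior_sim_params(),
                            coupling = coupling_params(),
                            loom = loom_params(),
                            n_nonescapers = 0L, seed = NULL) {
  n_mice <- as.integer(n_mice)
  if (n_mice < 2L) stop("need at least 2 mice")
  n_nonescapers <- as.integer(n_nonescapers)
  stopifnot(n_nonescapers >= 0L, n_nonescapers <= n_mice)
  if (!is.null(seed)) set.seed(seed)
  seeds <- sample.int(.Machine$integer.max - 1L, n_mice)
  sessions <- vector("list", n_mice)
  for (i in seq_len(n_mice)) {
    b <- behav
    b$escapes <- i <= n_mice - n_nonescapers
    sessions[[i]] <- simulate_session(phot, b, coupling, loom,
                                      seed = seeds[i])
  }
  r2 <- if (is.null(coupling)) NULL else
    c(latency = coupling_r2(coupling, "latency"),
      velocity = coupling_r2(coupling, "velocity"),
      acceleration = coupling_r2(coupling, "acceleration"))
  structure(list(sessions = sessions,
                 truth = list(master_seed = seed, mouse_seeds = seeds,
                              escaper = seq_len(n_mice) <= n_mice - n_nonescapers,
                              coupling = coupling,
                              population_r2 = r2)),
            class = "simulated_cohort")
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("Simulated cohort: %d mice (%d programmed escapers)\n",
              length(x$sessions), sum(x$truth$escaper)))
  invisible(x)
}
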