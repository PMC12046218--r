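# Session and cohort orchestration: correct -> z-score -> segment ->
# align -> test, with every threshold carried in one config object.

#' Analysis configuration
#'
#' All pipeline thresholds and windows in one nested list, suitable for
#' [write_config()] / [read_config()] round-trips. Values can be
#' overridden by name, e.g. `loom_config(behavior = list(escape_window = 8))`.
#'
#' @param ... named sections (`photometry`, `behavior`, `align`) whose
#'   entries override the defaults.
#' @return Nested named list of class `loom_config`.
#' @export
loom_config <- function(...) {
  cfg <- list(
    photometry = list(
      smooth_window = 0,       # optional dff low-pass before peak analysis (s)
      epoch_pre = 10,          # z-scoring epoch starts this long before trigger (s)
      epoch_post = 0,          # ... and ends this long after it: the default
                               # epoch is the pre-trigger baseline, so the
                               # normalization is not contaminated by the
                               # evoked response
      response_window = 1.0,   # post-onset peak search window (s)
      baseline_window = 1.0,   # pre-stimulus baseline epoch (s)
      min_prominence = 0.5,    # z units
      min_separation = 0.25),  # s
    behavior = list(
      smooth_window = 0.2,     # position smoothing (s)
      exploration_min = 300,   # free exploration before trigger (s)
      onset_threshold = 10,    # escape movement onset speed (cm/s)
      sustain = 0.2,           # supra-threshold duration at onset (s)
      onset_floor = 2,         # backtrack onset to where speed left this floor (cm/s)
      escape_window = 10,      # max disk-1-to-shelter time (s)
      bout_floor = 2,          # movement bout definition floor (cm/s)
      vigor_threshold = 20,    # vigorous bout peak (cm/s)
      merge_gap = 0.5,         # bout merge gap (s)
      freeze_ceiling = 1,      # immobility ceiling (cm/s)
      freeze_min_duration = 1),# s
    align = list(pre = 2, post = 5))
  over <- list(...)
  for (section in names(over)) {
    if (!section %in% names(cfg)) stop("unknown config section: ", section)
    for (key in names(over[[section]])) {
      if (!key %in% names(cfg[[section]]))
        stop("unknown config key: ", section, ".", key)
      cfg[[section]][[key]] <- over[[section]][[key]]
    }
  }
  class(cfg) <- c("loom_config", "list")
  cfg
}

#' Analyze one session
#'
#' Runs the full per-session pipeline: isosbestic correction, epoch
#' z-scoring around the trigger, per-disk stimulus responses and
#' pre-stimulus baseline, trajectory kinematics, escape detection and
#' escaper classification, pre-stimulus movement bouts (with the aligned
#' transient amplitude at the most vigorous bout), and post-stimulus
#' freezing. Deterministic given inputs and config.
#'
#' @param recording a [photometry_recording()].
#' @param track a [tracking_trace()].
#' @param train a [loom_schedule()] result; when `NULL` the trigger is
#'   detected from the track and the default train scheduled at it.
#' @param config a [loom_config()].
#' @param loom a [loom_params()] used when scheduling from a detected
#'   trigger.
#' @param mouse_id identifier carried into the result.
#' @return A `loom_session` list: `mouse_id`, `escaper`,
#'   `baseline_amplitude`, `disks` (per-disk amplitude/latency table),
#'   `escape` (`NULL` for non-escapers), `escape_amplitude`,
#'   `movement_bouts`, `movement_amplitude`, `freezing`, `trigger_time`,
#'   `trace`, `config`.
#' @export
run_session <- function(recording, track, train = NULL,
                        config = loom_config(), loom = loom_params(),
                        mouse_id = "m1") {
  stopifnot(inherits(recording, "photometry_recording"),
            inherits(track, "tracking_trace"),
            inherits(config, "loom_config"))
  pc <- config$photometry; bc <- config$behavior
  if (is.null(train)) {
    trig <- detect_trigger(track, exploration_min = bc$exploration_min)
    train <- loom_schedule(loom, trig)
  }
  trig <- train$trigger_time

  trace <- smooth_trace(isosbestic_correct(recording), pc$smooth_window)
  epoch <- c(max(trace$time[1L], trig - pc$epoch_pre),
             min(trace$time[length(trace$time)], trig + pc$epoch_post))
  trace <- zscore_epoch(trace, epoch)
  resp <- stimulus_response(trace, train,
                            response_window = pc$response_window,
                            min_prominence = pc$min_prominence,
                            min_separation = pc$min_separation)

  kin <- compute_kinematics(track, smooth_window = bc$smooth_window)
  escape <- detect_escape(kin, track, train,
                          onset_threshold = bc$onset_threshold,
                          sustain = bc$sustain,
                          onset_floor = bc$onset_floor,
                          escape_window = bc$escape_window)
  escaper <- classify_escaper(escape)

  peak_in_window <- function(t0) {
    win <- c(t0, t0 + pc$response_window - 1 / trace$sampling_rate)
    pk <- detect_peaks(trace, win, min_prominence = pc$min_prominence,
                       min_separation = pc$min_separation,
                       reference_time = t0)
    if (nrow(pk)) max(pk$amplitude) else {
      idx <- which(trace$time >= win[1L] & trace$time <= win[2L])
      if (length(idx)) max(trace$z[idx]) else NA_real_
    }
  }
  escape_amplitude <- if (escaper) peak_in_window(escape$onset) else NULL

  bouts <- detect_movement_bouts(kin, c(track$time[1L], trig),
                                 bout_floor = bc$bout_floor,
                                 vigor_threshold = bc$vigor_threshold,
                                 merge_gap = bc$merge_gap)
  movement_amplitude <- if (nrow(bouts)) {
    top <- bouts[which.max(bouts$peak_velocity), ]
    if (top$start - pc$epoch_pre >= trace$time[1L] &&
        top$start + pc$response_window <= max(trace$time))
      peak_in_window(top$start) else NA_real_
  } else NA_real_

  freezing <- detect_freezing(kin, c(trig, min(max(kin$time),
                                               trig + bc$escape_window)),
                              freeze_ceiling = bc$freeze_ceiling,
                              min_duration = bc$freeze_min_duration)

  structure(list(mouse_id = mouse_id, escaper = escaper,
                 baseline_amplitude = resp$baseline$amplitude,
                 disks = resp$disks,
                 escape = if (escaper) escape else NULL,
                 escape_amplitude = escape_amplitude,
                 movement_bouts = bouts,
                 movement_amplitude = movement_amplitude,
                 freezing = freezing,
                 trigger_time = trig, trace = trace, config = config),
            class = "loom_session")
}

#' @export
print.loom_session <- function(x, ...) {
  cat(sprintf("Session %s: trigger %.2f s, baseline %.2f z, disk-1 amplitude %.2f z, %s\n",
              x$mouse_id, x$trigger_time, x$baseline_amplitude,
              x$disks$amplitude[1L],
              if (x$escaper)
                sprintf("escape latency %.2f s (peak %.1f cm/s)",
                        x$escape$latency, x$escape$peak_velocity)
              else "no escape"))
  invisible(x)
}

#' Analyze a session produced by the simulator
#'
#' Convenience wrapper running [run_session()] on a
#' [simulate_session()] result, using the simulated train.
#'
#' @param sim a `simulated_session`.
#' @param config a [loom_config()].
#' @param mouse_id identifier.
#' @return A `loom_session`.
#' @export
run_simulated_session <- function(sim, config = loom_config(),
                                  mouse_id = "m1") {
  stopifnot(inherits(sim, "simulated_session"))
  run_session(sim$recording, sim$track, train = sim$train,
              config = config, mouse_id = mouse_id)
}

#' Analyze a session from its text files
#'
#' @param photometry_file,tracking_file CSV inputs (see
#'   [read_photometry()], [read_tracking()]).
#' @param events_file optional event file; a `trigger` row schedules the
#'   train there, otherwise the trigger is detected from tracking.
#' @param config a [loom_config()].
#' @param geometry an [arena_geometry()].
#' @param loom a [loom_params()].
#' @param mouse_id identifier.
#' @return A `loom_session`.
#' @export
run_session_files <- function(photometry_file, tracking_file,
                              events_file = NULL, config = loom_config(),
                              geometry = arena_geometry(),
                              loom = loom_params(), mouse_id = "m1") {
  rec <- read_photometry(photometry_file)
  track <- read_tracking(tracking_file, geometry)
  train <- NULL
  if (!is.null(events_file)) {
    ev <- read_events(events_file)
    rec$events <- ev
    tr <- ev$time_s[ev$label == "trigger"]
    if (length(tr)) train <- loom_schedule(loom, tr[1L])
  }
  run_session(rec, track, train = train, config = config, loom = loom,
              mouse_id = mouse_id)
}

#' Flatten sessions to a tidy long table
#'
#' One row per (mouse, measure): baseline and per-disk amplitudes, escape
#' kinematics, movement/freezing summaries.
#'
#' @param sessions list of `loom_session` results.
#' @return Data frame with columns `mouse_id`, `measure`, `value`.
#' @export
session_table <- function(sessions) {
  rows <- lapply(sessions, function(s) {
    m <- c(baseline_amplitude = s$baseline_amplitude,
           stats::setNames(s$disks$amplitude,
                           sprintf("disk%d_amplitude", s$disks$disk)),
           stats::setNames(s$disks$latency,
                           sprintf("disk%d_latency", s$disks$disk)),
           escaper = as.numeric(s$escaper),
           n_movement_bouts = nrow(s$movement_bouts),
           movement_amplitude = s$movement_amplitude,
           n_freeze_bouts = nrow(s$freezing))
    if (s$escaper)
      m <- c(m, escape_latency = s$escape$latency,
             escape_peak_velocity = s$escape$peak_velocity,
             escape_peak_acceleration = s$escape$peak_acceleration,
             escape_amplitude = s$escape_amplitude)
    data.frame(mouse_id = s$mouse_id, measure = names(m),
               value = unname(m), stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Cohort-level analysis
#'
#' Aggregates per-session results and runs the cohort statistics:
#' Pearson correlations between the disk-1 transient amplitude and each
#' escape metric in the escapers (skipped with a warning when fewer than
#' 3 escaped), a one-way repeated-measures ANOVA on baseline + per-disk
#' amplitudes with Bonferroni comparisons of each disk against baseline,
#' and the escaper-versus-nonescaper unpaired t test on the disk-1
#' amplitude (when both groups have n >= 2).
#'
#' @param sessions list of `loom_session` results (or a
#'   `simulated_cohort`, which is analyzed first).
#' @param config a [loom_config()] (used when `sessions` is a
#'   `simulated_cohort`).
#' @return A `loom_cohort` list: `sessions`, `table` (tidy long table),
#'   `correlations` (per metric), `anova`, `escaper_comparison`,
#'   `n_escapers`.
#' @export
run_cohort <- function(sessions, config = loom_config()) {
  if (inherits(sessions, "simulated_cohort"))
    sessions <- lapply(seq_along(sessions$sessions), function(i)
      run_simulated_session(sessions$sessions[[i]], config,
                            mouse_id = sprintf("m%02d", i)))
  stopifnot(length(sessions) >= 2L,
            all(vapply(sessions, inherits, logical(1), "loom_session")))

  esc <- vapply(sessions, function(s) s$escaper, logical(1))
  amp1 <- vapply(sessions, function(s) s$disks$amplitude[1L], numeric(1))

  correlations <- NULL
  if (sum(esc) >= 3L) {
    e <- sessions[esc]
    a <- amp1[esc]
    metrics <- list(
      latency = vapply(e, function(s) s$escape$latency, numeric(1)),
      peak_velocity = vapply(e, function(s) s$escape$peak_velocity, numeric(1)),
      peak_acceleration = vapply(e, function(s) s$escape$peak_acceleration,
                                 numeric(1)))
    correlations <- lapply(metrics, function(y) pearson_cor(a, y))
  } else {
    warning("fewer than 3 escapers; correlation stage skipped")
  }

  mat <- cbind(baseline = vapply(sessions, function(s) s$baseline_amplitude,
                                 numeric(1)),
               do.call(rbind, lapply(sessions, function(s) s$disks$amplitude)))
  colnames(mat) <- c("baseline", sprintf("disk%d", seq_len(ncol(mat) - 1L)))
  anova <- rm_anova(mat, baseline = 1L)

  escaper_comparison <- if (sum(esc) >= 2L && sum(!esc) >= 2L)
    t_test2(amp1[esc], amp1[!esc], paired = FALSE) else NULL

  structure(list(sessions = sessions, table = session_table(sessions),
                 correlations = correlations, anova = anova,
                 escaper_comparison = escaper_comparison,
                 n_escapers = sum(esc), amplitude_matrix = mat),
            class = "loom_cohort")
}

#' @export
print.loom_cohort <- function(x, ...) {
  cat(sprintf("Cohort: %d mice, %d escapers\n", length(x$sessions),
              x$n_escapers))
  if (!is.null(x$correlations)) {
    cat("  disk-1 amplitude vs escape metrics (escapers only):\n")
    for (nm in names(x$correlations)) {
      r <- x$correlations[[nm]]
      cat(sprintf("    %-18s R^2 = %.3f, p = %.4g (n = %d)\n",
                  nm, r$r_squared, r$p, r$n))
    }
  }
  a <- x$anova$table
  cat(sprintf("  amplitude ~ condition RM ANOVA: F(%d,%d) = %.3f, p = %.4g\n",
              a$df1[1L], a$df2[1L], a$F[1L], a$p[1L]))
  if (!is.null(x$escaper_comparison))
    cat(sprintf("  escapers vs nonescapers (disk-1): t(%g) = %.3f, p = %.4g\n",
                x$escaper_comparison$df, x$escaper_comparison$statistic,
                x$escaper_comparison$p))
  invisible(x)
}

#' @export
summary.loom_cohort <- function(object, ...) {
  print(object)
  invisible(object)
}

#' @export
coef.loom_cohort <- function(object, ...) {
  if (is.null(object$correlations)) return(numeric())
  vapply(object$correlations, function(r) r$r_squared, numeric(1))
}

#' Escape-count contingency comparison between two arms
#'
#' Builds the 2x2 escaped / did-not-escape table for two treatment arms
#' and applies the uncorrected Pearson chi-squared test.
#'
#' @param escaped_a,n_a escape count and group size of the first arm.
#' @param escaped_b,n_b second arm.
#' @return A [chi_squared_gof()] result plus `escape_rate_a`,
#'   `escape_rate_b` in percent.
#' @export
escape_contingency <- function(escaped_a, n_a, escaped_b, n_b) {
  stopifnot(escaped_a >= 0, escaped_b >= 0, escaped_a <= n_a,
            escaped_b <= n_b)
  tab <- matrix(c(escaped_a, escaped_b, n_a - escaped_a, n_b - escaped_b),
                nrow = 2,
                dimnames = list(arm = c("a", "b"),
                                outcome = c("escape", "no_escape")))
  res <- chi_squared_gof(tab)
  res$escape_rate_a <- 100 * escaped_a / n_a
  res$escape_rate_b <- 100 * escaped_b / n_b
  res
}
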