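# Trajectory kinematics and behavioral segmentation: threat-zone trigger
# detection, escape bouts, spontaneous movement bouts, freezing.

#' Arena geometry for the looming assay
#'
#' Rectangular arena with the coordinate origin at the threat-zone-end
#' corner and x running along the arena length. The threat zone is a square
#' section at the x = 0 end (under the display); the shelter occupies the
#' opposite end across the full width.
#'
#' @param length,width arena floor dimensions in cm.
#' @param threat_zone_size side of the square threat zone in cm.
#' @param shelter_depth extent of the shelter along x in cm.
#' @return An object of class `arena_geometry` with `threat_zone` and
#'   `shelter` rectangles (`xmin`, `xmax`, `ymin`, `ymax`).
#' @export
arena_geometry <- function(length = 61, width = 20.3, threat_zone_size = 20,
                           shelter_depth = 12) {
  stopifnot(length > 0, width > 0, threat_zone_size > 0, shelter_depth > 0,
            threat_zone_size + shelter_depth < length)
  structure(list(
    length = length, width = width,
    threat_zone = list(xmin = 0, xmax = threat_zone_size,
                       ymin = 0, ymax = min(threat_zone_size, width)),
    shelter = list(xmin = length - shelter_depth, xmax = length,
                   ymin = 0, ymax = width)),
    class = "arena_geometry")
}

.in_rect <- function(x, y, r) x >= r$xmin & x <= r$xmax & y >= r$ymin & y <= r$ymax

#' Zone membership tests
#'
#' @param x,y positions in cm (arena frame).
#' @param geometry an [arena_geometry()].
#' @return Logical vector.
#' @export
in_threat_zone <- function(x, y, geometry) .in_rect(x, y, geometry$threat_zone)

#' @rdname in_threat_zone
#' @export
in_shelter <- function(x, y, geometry) .in_rect(x, y, geometry$shelter)

#' Construct a tracking trace
#'
#' @param time strictly increasing timestamps in seconds.
#' @param x,y centroid position in cm, arena frame (origin at the
#'   threat-zone-end corner, x along the arena length). Positions may
#'   exceed the arena bounds by at most 0.5 cm (tracking jitter).
#' @param geometry an [arena_geometry()] used for validation.
#' @return An object of class `tracking_trace`.
#' @export
tracking_trace <- function(time, x, y, geometry = arena_geometry()) {
  stopifnot(is.numeric(time), is.numeric(x), is.numeric(y),
            length(time) == length(x), length(time) == length(y),
            length(time) >= 2L, inherits(geometry, "arena_geometry"))
  if (any(diff(time) <= 0)) stop("time must be strictly increasing")
  tol <- 0.5
  if (any(x < -tol | x > geometry$length + tol |
          y < -tol | y > geometry$width + tol))
    stop("positions outside the arena (tolerance 0.5 cm)")
  structure(list(time = time, x = x, y = y, geometry = geometry),
            class = "tracking_trace")
}

#' @export
print.tracking_trace <- function(x, ...) {
  cat(sprintf("Tracking trace: %d samples over %.1f s\n",
              length(x$time), diff(range(x$time))))
  invisible(x)
}

# Centered moving average of width (approximately) `window` seconds;
# shrinks symmetrically at the edges so no padding bias is introduced.
.smooth_ma <- function(v, half) {
  if (half < 1L) return(v)
  n <- length(v)
  cs <- cumsum(c(0, v))
  lo <- pmax(seq_len(n) - half, 1L)
  hi <- pmin(seq_len(n) + half, n)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Speed and acceleration from a tracking trace
#'
#' Positions are smoothed with a centered moving average before
#' differentiation; speed is the magnitude of the centered finite
#' difference of position, acceleration the centered difference of speed;
#' the endpoints use one-sided differences. Requires a uniform sampling
#' grid (1 percent tolerance).
#'
#' @param track a [tracking_trace()].
#' @param smooth_window moving-average width in seconds (0 disables
#'   smoothing). The 0.2 s default suppresses tracking jitter at 30 Hz
#'   without blunting sub-second escape ramps.
#' @return A `kinematics_trace`: `time`, `speed` (cm/s), `acceleration`
#'   (cm/s^2), `x`, `y` (smoothed), `sampling_rate`, `smooth_window`,
#'   `geometry`.
#' @export
compute_kinematics <- function(track, smooth_window = 0.2) {
  stopifnot(inherits(track, "tracking_trace"), smooth_window >= 0)
  t <- track$time
  if (length(t) < 3L) stop("need at least 3 samples")
  dt <- diff(t)
  if ((max(dt) - min(dt)) / mean(dt) > 0.01)
    stop("non-uniform sampling (beyond 1% tolerance)")
  dt <- mean(dt)
  fs <- 1 / dt
  half <- floor(smooth_window * fs / 2)
  xs <- .smooth_ma(track$x, half)
  ys <- .smooth_ma(track$y, half)
  n <- length(t)
  cdiff <- function(v) {
    d <- numeric(n)
    d[2:(n - 1L)] <- (v[3:n] - v[1:(n - 2L)]) / (2 * dt)
    d[1L] <- (v[2L] - v[1L]) / dt
    d[n] <- (v[n] - v[n - 1L]) / dt
    d
  }
  speed <- sqrt(cdiff(xs)^2 + cdiff(ys)^2)
  accel <- cdiff(speed)
  structure(list(time = t, speed = speed, acceleration = accel,
                 x = xs, y = ys, sampling_rate = fs,
                 smooth_window = smooth_window, geometry = track$geometry),
            class = "kinematics_trace")
}

#' Threat-zone trigger detection
#'
#' The stimulus is triggered by the first tracked position inside the
#' threat zone at or after the end of the free-exploration period.
#'
#' @param track a [tracking_trace()].
#' @param geometry an [arena_geometry()].
#' @param exploration_min free-exploration duration in seconds (default
#'   300, i.e. 5 min).
#' @return Trigger time in seconds.
#' @export
detect_trigger <- function(track, geometry = track$geometry,
                           exploration_min = 300) {
  stopifnot(inherits(track, "tracking_trace"), exploration_min >= 0)
  if (max(track$time) <= exploration_min)
    stop("track shorter than the exploration period")
  ok <- track$time >= exploration_min &
    in_threat_zone(track$x, track$y, geometry)
  if (!any(ok))
    stop("mouse never enters the threat zone after the exploration period")
  track$time[which(ok)[1L]]
}

# First index at/after `from_idx` where `speed >= thr` holds continuously
# for at least `sustain` seconds; NA when none exists before `to_idx`.
.sustained_crossing <- function(speed, time, thr, sustain, from_idx, to_idx) {
  need <- max(1L, ceiling(sustain / mean(diff(time))))
  run <- 0L
  for (i in from_idx:to_idx) {
    run <- if (speed[i] >= thr) run + 1L else 0L
    if (run >= need) return(i - run + 1L)
  }
  NA_integer_
}

#' Escape-bout detection
#'
#' An escape is a flight to shelter after the first looming disk: the
#' shelter must be entered within `escape_window` seconds of disk-1 onset,
#' anchored by the first time after disk-1 onset where speed exceeds
#' `onset_threshold` sustained for at least `sustain` seconds before
#' shelter entry. The reported onset is then backtracked from that
#' threshold crossing to the moment speed last left the resting floor
#' (`onset_floor`), i.e. movement initiation, so the latency does not
#' inherit the ramp's time-to-threshold. Peak velocity and acceleration
#' are measured between onset and shelter entry. A trial in which the
#' mouse is already inside the shelter at disk-1 onset is invalid
#' (warning, `NULL`).
#'
#' @param kin a [compute_kinematics()] result.
#' @param track the corresponding [tracking_trace()].
#' @param train a [loom_schedule()] result.
#' @param geometry an [arena_geometry()].
#' @param onset_threshold speed threshold anchoring movement onset, cm/s.
#' @param sustain minimum supra-threshold duration, seconds.
#' @param onset_floor resting-speed floor the onset is backtracked to, cm/s.
#' @param escape_window maximum disk-1-onset-to-shelter-entry time, seconds.
#' @return An `escape_bout` list (`onset`, `latency`, `peak_velocity`,
#'   `peak_acceleration`, `shelter_entry`) or `NULL` when the mouse does
#'   not reach the shelter in time.
#' @export
detect_escape <- function(kin, track, train, geometry = track$geometry,
                          onset_threshold = 10, sustain = 0.2,
                          onset_floor = 2, escape_window = 10) {
  stopifnot(inherits(kin, "kinematics_trace"),
            inherits(track, "tracking_trace"),
            inherits(train, "stimulus_train"))
  d1 <- train$disk_onsets[1L]
  if (max(track$time) < d1 + escape_window)
    stop("trace must cover the stimulus train plus the escape window")
  i0 <- which(track$time >= d1)[1L]
  if (is.na(i0)) stop("malformed train: disk-1 onset beyond the trace")
  if (in_shelter(track$x[i0], track$y[i0], geometry)) {
    warning("invalid trial: mouse inside the shelter at disk-1 onset")
    return(NULL)
  }
  after <- which(track$time >= d1 & track$time <= d1 + escape_window)
  inside <- in_shelter(track$x[after], track$y[after], geometry)
  if (!any(inside)) return(NULL)
  entry_idx <- after[which(inside)[1L]]
  entry <- track$time[entry_idx]
  onset_idx <- .sustained_crossing(kin$speed, kin$time, onset_threshold,
                                   sustain, i0, entry_idx)
  if (is.na(onset_idx)) return(NULL)
  # movement initiation: last sub-floor sample before the anchor crossing
  while (onset_idx > i0 && kin$speed[onset_idx - 1L] >= onset_floor)
    onset_idx <- onset_idx - 1L
  onset <- kin$time[onset_idx]
  seg <- onset_idx:entry_idx
  structure(list(onset = onset, latency = onset - d1,
                 peak_velocity = max(kin$speed[seg]),
                 peak_acceleration = max(kin$acceleration[seg]),
                 shelter_entry = entry),
            class = "escape_bout")
}

#' @export
print.escape_bout <- function(x, ...) {
  cat(sprintf("Escape bout: latency %.2f s, peak velocity %.1f cm/s, peak acceleration %.1f cm/s^2, shelter entry %.2f s\n",
              x$latency, x$peak_velocity, x$peak_acceleration, x$shelter_entry))
  invisible(x)
}

# Maximal intervals where `flag` is TRUE, as an index matrix (start, end).
.runs <- function(flag) {
  r <- rle(flag)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  cbind(start = starts[r$values], end = ends[r$values])
}

#' Spontaneous movement-bout detection
#'
#' Maximal intervals with speed at or above `bout_floor`, merged when
#' separated by gaps shorter than `merge_gap`, and retained when the bout
#' contains a peak at or above `vigor_threshold`.
#'
#' @param kin a [compute_kinematics()] result.
#' @param window `(start, end)` seconds to search (e.g. the pre-stimulus
#'   exploration period).
#' @param bout_floor speed floor defining a bout, cm/s.
#' @param vigor_threshold minimum peak speed for a vigorous bout, cm/s.
#' @param merge_gap bouts closer than this are merged, seconds.
#' @return Data frame `start`, `end`, `peak_velocity`, `peak_time`; zero
#'   rows when nothing qualifies.
#' @export
detect_movement_bouts <- function(kin, window, bout_floor = 2,
                                  vigor_threshold = 20, merge_gap = 0.5) {
  stopifnot(inherits(kin, "kinematics_trace"), length(window) == 2L)
  idx <- which(kin$time >= window[1L] & kin$time <= window[2L])
  if (!length(idx)) stop("empty window")
  sp <- kin$speed[idx]
  tm <- kin$time[idx]
  runs <- .runs(sp >= bout_floor)
  if (!nrow(runs))
    return(data.frame(start = numeric(), end = numeric(),
                      peak_velocity = numeric(), peak_time = numeric()))
  # merge runs separated by sub-threshold gaps shorter than merge_gap
  merged <- runs[1L, , drop = FALSE]
  if (nrow(runs) > 1L) for (i in 2:nrow(runs)) {
    gap <- tm[runs[i, "start"]] - tm[merged[nrow(merged), "end"]]
    if (gap < merge_gap) {
      merged[nrow(merged), "end"] <- runs[i, "end"]
    } else {
      merged <- rbind(merged, runs[i, , drop = FALSE])
    }
  }
  rows <- lapply(seq_len(nrow(merged)), function(i) {
    seg <- merged[i, "start"]:merged[i, "end"]
    j <- seg[which.max(sp[seg])]
    data.frame(start = tm[merged[i, "start"]], end = tm[merged[i, "end"]],
               peak_velocity = sp[j], peak_time = tm[j])
  })
  out <- do.call(rbind, rows)
  out[out$peak_velocity >= vigor_threshold, , drop = FALSE]
}

#' Freezing detection
#'
#' Maximal intervals with speed below `freeze_ceiling` lasting at least
#' `min_duration`, with the mouse outside the shelter throughout
#' (immobility inside the shelter is sheltering, not freezing).
#'
#' @param kin a [compute_kinematics()] result.
#' @param window `(start, end)` seconds to search.
#' @param freeze_ceiling immobility speed ceiling, cm/s.
#' @param min_duration minimum bout duration, seconds.
#' @param geometry an [arena_geometry()].
#' @return Data frame `start`, `end`, `mean_speed`; zero rows when none.
#' @export
detect_freezing <- function(kin, window, freeze_ceiling = 1,
                            min_duration = 1, geometry = kin$geometry) {
  stopifnot(inherits(kin, "kinematics_trace"), length(window) == 2L)
  idx <- which(kin$time >= window[1L] & kin$time <= window[2L])
  if (!length(idx)) stop("empty window")
  still <- kin$speed[idx] < freeze_ceiling &
    !in_shelter(kin$x[idx], kin$y[idx], geometry)
  runs <- .runs(still)
  out <- data.frame(start = numeric(), end = numeric(), mean_speed = numeric())
  for (i in seq_len(nrow(runs))) {
    seg <- runs[i, "start"]:runs[i, "end"]
    dur <- kin$time[idx[runs[i, "end"]]] - kin$time[idx[runs[i, "start"]]]
    if (dur >= min_duration)
      out <- rbind(out, data.frame(start = kin$time[idx[runs[i, "start"]]],
                                   end = kin$time[idx[runs[i, "end"]]],
                                   mean_speed = mean(kin$speed[idx[seg]])))
  }
  out
}

#' Escaper classification
#'
#' A mouse is an escaper when its threat trial produced an escape bout.
#'
#' @param escape an [detect_escape()] result (`escape_bout` or `NULL`).
#' @return Logical.
#' @export
classify_escaper <- function(escape) {
  inherits(escape, "escape_bout")
}
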