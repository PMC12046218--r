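# Two-channel photometry: reference-channel (isosbestic) artifact
# correction, epoch z-scoring, transient detection, and event alignment.

#' Construct a two-channel photometry recording
#'
#' Container for a raw recording: a uniform time grid, the signal channel
#' (465 nm excitation), the isosbestic reference channel (405 nm
#' excitation), and labelled event timestamps.
#'
#' @param time strictly increasing time grid in seconds (uniform).
#' @param f465 signal-channel fluorescence (a.u.).
#' @param f405 reference-channel fluorescence (a.u.).
#' @param sampling_rate sampling rate in Hz; must agree with the grid
#'   spacing to 1e-6 relative tolerance.
#' @param events optional data frame with columns `label`, `time_s`.
#' @return An object of class `photometry_recording`.
#' @export
photometry_recording <- function(time, f465, f405, sampling_rate,
                                 events = NULL) {
  stopifnot(is.numeric(time), is.numeric(f465), is.numeric(f405),
            length(time) == length(f465), length(time) == length(f405),
            length(time) >= 2L, is.numeric(sampling_rate),
            sampling_rate > 0)
  dt <- diff(time)
  if (any(dt <= 0)) stop("time must be strictly increasing")
  if (max(abs(dt * sampling_rate - 1)) > 1e-6)
    stop("sampling_rate inconsistent with the time grid")
  if (!is.null(events)) {
    stopifnot(is.data.frame(events), all(c("label", "time_s") %in% names(events)))
  } else {
    events <- data.frame(label = character(), time_s = numeric())
  }
  structure(list(time = time, f465 = f465, f405 = f405,
                 sampling_rate = sampling_rate, events = events),
            class = "photometry_recording")
}

#' @export
print.photometry_recording <- function(x, ...) {
  cat(sprintf("Photometry recording: %d samples at %g Hz (%.1f s), %d events\n",
              length(x$time), x$sampling_rate, diff(range(x$time)),
              nrow(x$events)))
  invisible(x)
}

#' Isosbestic artifact correction
#'
#' Fits the first-order (linear) model `f465 ~ slope * f405 + intercept` by
#' ordinary least squares and subtracts the fitted reference model from the
#' signal channel: `dff = f465 - (slope * f405 + intercept)`. Because
#' motion artifacts and photobleaching appear in both excitation channels
#' while sensor transients appear only in the signal channel, the residual
#' retains the transients and sheds the shared artifact.
#'
#' @param rec a [photometry_recording()].
#' @return An object of class `corrected_trace` with fields `time`, `dff`,
#'   `z` (NULL until [zscore_epoch()] is applied), `fit_slope`,
#'   `fit_intercept`, `sampling_rate`, `events`, `epoch_window`.
#' @export
isosbestic_correct <- function(rec) {
  stopifnot(inherits(rec, "photometry_recording"))
  if (length(rec$time) < 10L) stop("need at least 10 samples for the reference fit")
  bad <- which(!is.finite(rec$f465) | !is.finite(rec$f405))
  if (length(bad))
    stop("non-finite sample at index ", bad[1L], "; clean the recording first")
  if (stats::var(rec$f405) < 1e-12 * max(1, mean(rec$f405)^2))
    stop("degenerate fit: reference channel is (near-)constant")
  fit <- stats::lm.fit(cbind(1, rec$f405), rec$f465)
  intercept <- fit$coefficients[[1L]]
  slope <- fit$coefficients[[2L]]
  dff <- rec$f465 - (slope * rec$f405 + intercept)
  structure(list(time = rec$time, dff = dff, z = NULL,
                 fit_slope = slope, fit_intercept = intercept,
                 sampling_rate = rec$sampling_rate, events = rec$events,
                 epoch_window = NULL),
            class = "corrected_trace")
}

#' @export
print.corrected_trace <- function(x, ...) {
  cat(sprintf("Corrected trace: %d samples at %g Hz; fit slope %.4g, intercept %.4g\n",
              length(x$time), x$sampling_rate, x$fit_slope, x$fit_intercept))
  if (!is.null(x$z))
    cat(sprintf("  z-scored in epoch [%.2f, %.2f] s\n",
                x$epoch_window[1L], x$epoch_window[2L]))
  invisible(x)
}

#' @export
plot.corrected_trace <- function(x, ...) {
  y <- if (is.null(x$z)) x$dff else x$z
  ylab <- if (is.null(x$z)) expression(Delta * F ~ "(a.u.)") else "z score"
  graphics::plot(x$time, y, type = "l", xlab = "time (s)", ylab = ylab, ...)
  if (nrow(x$events))
    graphics::abline(v = x$events$time_s, col = "grey60", lty = 2)
  invisible(x)
}

#' Low-pass smoothing of a corrected trace
#'
#' Centered moving average applied to the dff series (any existing z
#' stage is invalidated and must be recomputed). A window of a few tens
#' of milliseconds suppresses single-sample noise excursions while
#' attenuating a 0.1-s-rise sensor transient by about one percent. Off by
#' default in the pipeline: once the trace is epoch z-scored the white
#' noise is normalized away with everything else, and smoothing mainly
#' amplifies the relative weight of the slow residual artifact; it is
#' useful when the white-noise floor genuinely dominates.
#'
#' @param trace a [isosbestic_correct()] result.
#' @param window moving-average width in seconds (0 returns the trace
#'   unchanged).
#' @return The `corrected_trace` with smoothed `dff` and
#'   `smooth_window` recorded.
#' @export
smooth_trace <- function(trace, window = 0.05) {
  stopifnot(inherits(trace, "corrected_trace"), window >= 0)
  half <- floor(window * trace$sampling_rate / 2)
  if (half >= 1L) {
    trace$dff <- .smooth_ma(trace$dff, half)
    trace$z <- NULL
    trace$epoch_window <- NULL
  }
  trace$smooth_window <- window
  trace
}

#' Epoch z-scoring of a corrected trace
#'
#' Standardizes the whole dff trace using the mean and sample standard
#' deviation (n - 1 denominator) computed from the samples inside the epoch
#' window only. Within the window the resulting z trace has mean 0 and
#' sample sd 1.
#'
#' @param trace a [isosbestic_correct()] result.
#' @param window numeric length-2 `(start, end)` in seconds.
#' @return The `corrected_trace` with `z` and `epoch_window` filled in.
#' @export
zscore_epoch <- function(trace, window) {
  stopifnot(inherits(trace, "corrected_trace"), is.numeric(window),
            length(window) == 2L, window[2L] > window[1L])
  idx <- which(trace$time >= window[1L] & trace$time <= window[2L])
  if (length(idx) < 3L) stop("epoch window must contain at least 3 samples")
  m <- mean(trace$dff[idx])
  s <- stats::sd(trace$dff[idx])
  if (s == 0) stop("dff is constant within the epoch window")
  trace$z <- (trace$dff - m) / s
  trace$epoch_window <- as.numeric(window)
  trace
}

# Local maxima with earliest-sample tie-breaking on plateaus: sample i is a
# peak when it exceeds its left neighbour and is >= its right neighbour,
# and is the first sample of any flat run.
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3L) return(integer())
  i <- 2:(n - 1L)
  which(x[i] > x[i - 1L] & x[i] >= x[i + 1L]) + 1L
}

# Topographic prominence of peak at index p: height above the higher of the
# two saddle minima between p and the nearest strictly higher sample (or
# the trace end) on each side.
.prominence <- function(x, p) {
  n <- length(x)
  left <- if (p == 1L) x[p] else {
    higher <- which(x[seq_len(p - 1L)] > x[p])
    lo <- if (length(higher)) max(higher) + 1L else 1L
    min(x[lo:p])
  }
  right <- if (p == n) x[p] else {
    after <- (p + 1L):n
    higher <- after[x[after] > x[p]]
    hi <- if (length(higher)) min(higher) - 1L else n
    min(x[p:hi])
  }
  x[p] - max(left, right)
}

#' Detect transient peaks in a z-scored trace
#'
#' Local maxima within a search window that clear a topographic prominence
#' floor, thinned so that retained peaks are separated by a minimum time:
#' peaks are considered in decreasing amplitude order and a peak closer
#' than `min_separation` to an already retained peak is dropped. Plateau
#' ties resolve to the earliest sample. Prominence is computed on the full
#' trace (the window only selects peaks), so a transient near a window
#' edge is not penalized by the truncation.
#'
#' @param trace a z-scored [corrected_trace][zscore_epoch()].
#' @param search_window `(start, end)` seconds; must overlap the trace.
#' @param min_prominence minimum topographic prominence in z units.
#' @param min_separation minimum spacing between retained peaks, seconds.
#' @param reference_time optional event time used to report latencies.
#' @param reference_label label recorded on the returned events.
#' @return A data frame of class `peak_events` with columns `time`,
#'   `amplitude`, `latency`, `reference_label`, sorted by time; zero rows
#'   when nothing qualifies.
#' @export
detect_peaks <- function(trace, search_window,
                         min_prominence = 0.5, min_separation = 0.25,
                         reference_time = NA_real_,
                         reference_label = NA_character_) {
  stopifnot(inherits(trace, "corrected_trace"), !is.null(trace$z),
            is.numeric(search_window), length(search_window) == 2L,
            min_prominence >= 0, min_separation >= 0)
  idx <- which(trace$time >= search_window[1L] & trace$time <= search_window[2L])
  if (!length(idx)) stop("empty search window")
  z <- trace$z
  cand <- .local_maxima(z)
  cand <- cand[cand %in% idx]
  if (length(cand)) {
    prom <- vapply(cand, function(p) .prominence(z, p), numeric(1))
    cand <- cand[prom >= min_prominence]
  }
  keep <- integer()
  for (p in cand[order(-z[cand], cand)]) {
    if (!length(keep) ||
        all(abs(trace$time[p] - trace$time[keep]) >= min_separation))
      keep <- c(keep, p)
  }
  keep <- sort(keep)
  out <- data.frame(time = trace$time[keep], amplitude = z[keep],
                    latency = trace$time[keep] - reference_time,
                    reference_label = rep(reference_label, length(keep)),
                    stringsAsFactors = FALSE)
  class(out) <- c("peak_events", "data.frame")
  out
}

#' Pre-stimulus baseline peak amplitude
#'
#' The amplitude of the largest detected transient peak within the 1-s
#' epoch immediately before stimulus onset, approximating the size of
#' spontaneous release events and fluorescence noise. When no local maximum
#' clears the prominence floor in that window (e.g. a monotone ramp), the
#' maximum sample value in the window is returned and flagged as a
#' fallback.
#'
#' @param trace a z-scored [corrected_trace][zscore_epoch()].
#' @param stimulus_onset onset time in seconds; at least `baseline_window`
#'   seconds of trace must precede it.
#' @param baseline_window length of the pre-onset epoch, seconds.
#' @param min_prominence,min_separation passed to [detect_peaks()].
#' @return A list: `amplitude` (z units), `time`, `fallback` (TRUE when the
#'   window maximum was used because no peak qualified).
#' @export
baseline_peak <- function(trace, stimulus_onset, baseline_window = 1.0,
                          min_prominence = 0.5, min_separation = 0.25) {
  stopifnot(inherits(trace, "corrected_trace"), !is.null(trace$z))
  if (stimulus_onset - baseline_window < trace$time[1L])
    stop("stimulus onset within the first ", baseline_window,
         " s of the trace; no baseline epoch available")
  win <- c(stimulus_onset - baseline_window, stimulus_onset)
  idx <- which(trace$time >= win[1L] & trace$time < win[2L])
  pk <- detect_peaks(trace, c(win[1L], trace$time[max(idx)]),
                     min_prominence = min_prominence,
                     min_separation = min_separation,
                     reference_time = stimulus_onset,
                     reference_label = "baseline")
  if (nrow(pk)) {
    j <- which.max(pk$amplitude)
    list(amplitude = pk$amplitude[j], time = pk$time[j], fallback = FALSE)
  } else {
    j <- idx[which.max(trace$z[idx])]
    list(amplitude = trace$z[j], time = trace$time[j], fallback = TRUE)
  }
}

#' Event-aligned response matrix
#'
#' Extracts a fixed peri-event window around each event by nearest-sample
#' indexing (no interpolation) and stacks the snippets on a common
#' relative-time grid. Events without full pre/post coverage are dropped
#' (recorded in `dropped`); mean and SEM (sd / sqrt(n)) rows are appended.
#'
#' @param trace a z-scored [corrected_trace][zscore_epoch()].
#' @param events numeric vector of event times in seconds.
#' @param pre,post window extent before / after each event, seconds (>= 0).
#' @return An `event_aligned` list: `relative_time`, `values` (one row per
#'   surviving event), `mean`, `sem`, `events`, `dropped`.
#' @export
align_to_events <- function(trace, events, pre = 2, post = 5) {
  stopifnot(inherits(trace, "corrected_trace"), !is.null(trace$z),
            is.numeric(events), pre >= 0, post >= 0)
  fs <- trace$sampling_rate
  n_pre <- round(pre * fs); n_post <- round(post * fs)
  rel <- (-n_pre:n_post) / fs
  n <- length(trace$time)
  rows <- list(); kept <- numeric(); dropped <- numeric()
  for (ev in events) {
    ctr <- which.min(abs(trace$time - ev))
    if (ctr - n_pre < 1L || ctr + n_post > n) {
      dropped <- c(dropped, ev)
      next
    }
    rows[[length(rows) + 1L]] <- trace$z[(ctr - n_pre):(ctr + n_post)]
    kept <- c(kept, ev)
  }
  if (!length(rows))
    stop("no events with full pre/post coverage")
  values <- do.call(rbind, rows)
  sem <- if (nrow(values) == 1L) rep(0, ncol(values)) else
    apply(values, 2L, stats::sd) / sqrt(nrow(values))
  structure(list(relative_time = rel, values = values,
                 mean = colMeans(values),
                 sem = sem,
                 events = kept, dropped = dropped),
            class = "event_aligned")
}

#' @export
print.event_aligned <- function(x, ...) {
  cat(sprintf("Event-aligned matrix: %d events x %d samples ([%.2f, %.2f] s)%s\n",
              nrow(x$values), ncol(x$values), min(x$relative_time),
              max(x$relative_time),
              if (length(x$dropped)) sprintf(", %d dropped", length(x$dropped)) else ""))
  invisible(x)
}

#' @export
plot.event_aligned <- function(x, ...) {
  graphics::plot(x$relative_time, x$mean, type = "l",
                 ylim = range(x$mean - x$sem, x$mean + x$sem),
                 xlab = "time from event (s)", ylab = "z score", ...)
  graphics::lines(x$relative_time, x$mean + x$sem, col = "grey60")
  graphics::lines(x$relative_time, x$mean - x$sem, col = "grey60")
  graphics::abline(v = 0, lty = 2)
  invisible(x)
}

#' Per-disk stimulus-evoked response amplitudes
#'
#' For each disk onset in the train, the largest detected peak in the
#' half-open window `[onset, onset + response_window)` (the same
#' convention as the pre-stimulus baseline window, so the two statistics
#' are exchangeable under the null); when no local maximum clears the
#' prominence floor, the window maximum sample is used (flagged), so the
#' statistic is defined on every trial and matches the baseline statistic's
#' construction. Also returns the pre-train baseline peak of disk 1. The
#' default 1-s response window brackets the sub-second latencies typical of
#' dopamine-sensor transients at looming-disk onset.
#'
#' @param trace a z-scored [corrected_trace][zscore_epoch()].
#' @param train a [loom_schedule()] result; must be fully covered by the
#'   trace, with at least 1 s of trace before the first disk.
#' @param response_window seconds after each disk onset to search.
#' @param min_prominence,min_separation passed to [detect_peaks()].
#' @return A `stimulus_response` list: `disks` (data frame `disk`, `onset`,
#'   `amplitude`, `peak_time`, `latency`, `fallback`) and `baseline` (the
#'   [baseline_peak()] of disk 1).
#' @export
stimulus_response <- function(trace, train, response_window = 1.0,
                              min_prominence = 0.5, min_separation = 0.25) {
  stopifnot(inherits(trace, "corrected_trace"), !is.null(trace$z),
            inherits(train, "stimulus_train"), response_window > 0)
  if (max(train$disk_onsets) + response_window > max(trace$time))
    stop("stimulus train extends past the end of the trace")
  half_open <- response_window - 1 / trace$sampling_rate
  rows <- lapply(seq_along(train$disk_onsets), function(k) {
    onset <- train$disk_onsets[k]
    pk <- detect_peaks(trace, c(onset, onset + half_open),
                       min_prominence = min_prominence,
                       min_separation = min_separation,
                       reference_time = onset,
                       reference_label = sprintf("disk%d", k))
    if (nrow(pk)) {
      j <- which.max(pk$amplitude)
      data.frame(disk = k, onset = onset, amplitude = pk$amplitude[j],
                 peak_time = pk$time[j], latency = pk$latency[j],
                 fallback = FALSE)
    } else {
      idx <- which(trace$time >= onset & trace$time < onset + response_window)
      j <- idx[which.max(trace$z[idx])]
      data.frame(disk = k, onset = onset, amplitude = trace$z[j],
                 peak_time = trace$time[j], latency = trace$time[j] - onset,
                 fallback = TRUE)
    }
  })
  structure(list(disks = do.call(rbind, rows),
                 baseline = baseline_peak(trace, train$disk_onsets[1L],
                                          min_prominence = min_prominence,
                                          min_separation = min_separation)),
            class = "stimulus_response")
}

#' @export
print.stimulus_response <- function(x, ...) {
  cat("Stimulus-evoked response (z units):\n")
  cat(sprintf("  baseline: %.3f%s\n", x$baseline$amplitude,
              if (x$baseline$fallback) " (window max fallback)" else ""))
  for (i in seq_len(nrow(x$disks)))
    cat(sprintf("  disk %d: amplitude %.3f, latency %.3f s\n",
                x$disks$disk[i], x$disks$amplitude[i], x$disks$latency[i]))
  invisible(x)
}
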