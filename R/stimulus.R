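# Looming-disk protocol: trigger-locked train scheduling, disk expansion,
# and overhead viewing geometry.

#' Looming stimulus parameters
#'
#' Parameters of the overhead looming-disk protocol: a train of dark (or
#' contrast-inverted) disks, each expanding linearly from zero to its final
#' diameter and then holding at full size, presented with a fixed
#' inter-stimulus interval.
#'
#' @param n_disks number of disks in the train.
#' @param expand_duration seconds of linear expansion from 0 to
#'   `final_diameter`.
#' @param hold_duration seconds the disk stays at full expansion.
#' @param isi inter-stimulus interval in seconds, measured offset-to-onset.
#' @param final_diameter full disk diameter in cm.
#' @param display_height height of the display above the arena floor in cm;
#'   used as the nominal viewing distance.
#' @param contrast `"dark"` (black disk on light background, threatening) or
#'   `"inverted"` (light disk on black background, non-threatening).
#' @return An object of class `loom_params`.
#' @export
#' @examples
#' loom_params()
loom_params <- function(n_disks = 5L, expand_duration = 0.25,
                        hold_duration = 0.25, isi = 0.5,
                        final_diameter = 19.5, display_height = 40.5,
                        contrast = c("dark", "inverted")) {
  contrast <- match.arg(contrast)
  n_disks <- as.integer(n_disks)
  stopifnot(n_disks >= 1L, expand_duration > 0, hold_duration > 0, isi > 0,
            final_diameter > 0, display_height > 0)
  structure(list(n_disks = n_disks, expand_duration = expand_duration,
                 hold_duration = hold_duration, isi = isi,
                 final_diameter = final_diameter,
                 display_height = display_height, contrast = contrast),
            class = "loom_params")
}

#' Schedule a looming-disk train from a trigger time
#'
#' Disk `k` (0-based) starts at
#' `trigger_time + k * (expand_duration + hold_duration + isi)`; each disk
#' lasts `expand_duration + hold_duration`. The ISI is interpreted as the
#' offset-to-onset gap, so with the defaults (0.25 s expansion + 0.25 s hold
#' + 0.5 s ISI) the disk onsets fall on a 1-s grid.
#'
#' @param params a [loom_params()] object.
#' @param trigger_time trigger timestamp in seconds (>= 0).
#' @return An object of class `stimulus_train` with fields `trigger_time`,
#'   `disk_onsets`, `disk_offsets`, `contrast`, and the generating `params`.
#' @export
#' @examples
#' loom_schedule(loom_params(), trigger_time = 300)
loom_schedule <- function(params = loom_params(), trigger_time) {
  stopifnot(inherits(params, "loom_params"), is.numeric(trigger_time),
            length(trigger_time) == 1L, is.finite(trigger_time),
            trigger_time >= 0)
  period <- params$expand_duration + params$hold_duration + params$isi
  onsets <- trigger_time + (seq_len(params$n_disks) - 1L) * period
  offsets <- onsets + params$expand_duration + params$hold_duration
  structure(list(trigger_time = trigger_time, disk_onsets = onsets,
                 disk_offsets = offsets, contrast = params$contrast,
                 params = params),
            class = "stimulus_train")
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf("Looming stimulus train (%s disks, %s contrast)\n",
              length(x$disk_onsets), x$contrast))
  cat(sprintf("  trigger at %.3f s; onsets: %s\n", x$trigger_time,
              paste(sprintf("%.2f", x$disk_onsets), collapse = ", ")))
  invisible(x)
}

#' Disk diameter at a time within one stimulus
#'
#' Linear ramp from 0 to `final_diameter` over `expand_duration`, then
#' constant during the hold.
#'
#' @param t_rel time in seconds relative to disk onset; must lie in
#'   `[0, expand_duration + hold_duration]`.
#' @param params a [loom_params()] object.
#' @return Diameter in cm (vectorized over `t_rel`).
#' @export
disk_diameter <- function(t_rel, params = loom_params()) {
  stopifnot(inherits(params, "loom_params"), is.numeric(t_rel))
  dur <- params$expand_duration + params$hold_duration
  if (any(t_rel < 0 | t_rel > dur))
    stop("t_rel outside the stimulus window [0, ", dur, "]")
  pmin(t_rel / params$expand_duration, 1) * params$final_diameter
}

#' Full visual angle subtended by a disk
#'
#' The full angle subtended at the eye by a disk of the given diameter seen
#' face-on at the given distance: `2 * atan(diameter / (2 * distance))`,
#' in degrees. With the default geometry (19.5 cm disk, 40.5 cm display
#' height) the fully expanded disk subtends about 27 degrees.
#'
#' @param diameter disk diameter in cm (>= 0).
#' @param viewing_distance distance from eye to disk plane in cm (> 0).
#' @return Angle in degrees, in `[0, 180)`; vectorized.
#' @export
#' @examples
#' visual_angle(19.5, 40.5)
visual_angle <- function(diameter, viewing_distance) {
  stopifnot(is.numeric(diameter), is.numeric(viewing_distance))
  if (any(diameter < 0)) stop("diameter must be >= 0")
  if (any(viewing_distance <= 0)) stop("viewing_distance must be > 0")
  2 * atan(diameter / (2 * viewing_distance)) * 180 / pi
}

#' Recover the disk index for a timestamp inside a train
#'
#' @param time timestamp in seconds.
#' @param train a [loom_schedule()] result.
#' @return 1-based disk index, or `NA_integer_` when the timestamp does not
#'   fall inside any disk presentation (e.g. during an ISI); vectorized.
#' @export
disk_index <- function(time, train) {
  stopifnot(inherits(train, "stimulus_train"))
  vapply(time, function(tt) {
    k <- which(tt >= train$disk_onsets & tt <= train$disk_offsets)
    if (length(k)) k[1L] else NA_integer_
  }, integer(1))
}
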