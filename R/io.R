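# Delimited-text readers and writers for the session file formats:
# photometry (time,f465,f405), tracking (time,x,y), labelled event
# timestamps, corrected traces with a metadata header block, bout/peak
# tables, the flat sectioned key = value config, and the ground-truth
# sidecar.

# Field-count validation so malformed rows are reported with file + line.
.check_fields <- function(path, n_expected) {
  nf <- utils::count.fields(path, sep = ",", comment.char = "#")
  bad <- which(nf != n_expected)
  if (length(bad))
    stop(sprintf("parse error in '%s' at line %d: expected %d fields, found %d",
                 path, bad[1L], n_expected, nf[bad[1L]]))
}

.read_delim_checked <- function(path, columns) {
  if (!file.exists(path)) stop("file not found: ", path)
  .check_fields(path, length(columns))
  df <- utils::read.csv(path, comment.char = "#", stringsAsFactors = FALSE)
  missing <- setdiff(columns, names(df))
  if (length(missing))
    stop(sprintf("parse error in '%s': missing column(s) %s",
                 path, paste(missing, collapse = ", ")))
  df
}

#' Read / write photometry as delimited text
#'
#' CSV with header columns `time`, `f465`, `f405`.
#'
#' @param path file path.
#' @param sampling_rate Hz; inferred from the median grid spacing when
#'   omitted.
#' @param events optional events data frame (`label`, `time_s`) to attach.
#' @return [read_photometry()]: a [photometry_recording()].
#' @export
read_photometry <- function(path, sampling_rate = NULL, events = NULL) {
  df <- .read_delim_checked(path, c("time", "f465", "f405"))
  if (is.null(sampling_rate))
    sampling_rate <- 1 / stats::median(diff(df$time))
  photometry_recording(df$time, df$f465, df$f405, sampling_rate,
                       events = events)
}

#' @rdname read_photometry
#' @param rec a [photometry_recording()].
#' @export
write_photometry <- function(rec, path) {
  stopifnot(inherits(rec, "photometry_recording"))
  utils::write.csv(data.frame(time = rec$time, f465 = rec$f465,
                              f405 = rec$f405),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write tracking as delimited text
#'
#' CSV with header columns `time`, `x`, `y` (cm, arena frame).
#'
#' @param path file path.
#' @param geometry an [arena_geometry()].
#' @return [read_tracking()]: a [tracking_trace()].
#' @export
read_tracking <- function(path, geometry = arena_geometry()) {
  df <- .read_delim_checked(path, c("time", "x", "y"))
  tracking_trace(df$time, df$x, df$y, geometry)
}

#' @rdname read_tracking
#' @param track a [tracking_trace()].
#' @export
write_tracking <- function(track, path) {
  stopifnot(inherits(track, "tracking_trace"))
  utils::write.csv(data.frame(time = track$time, x = track$x, y = track$y),
                   path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write labelled event timestamps
#'
#' Two-column comma-delimited text with header `label`, `time_s` (e.g.
#' `trigger`, `disk1` .. `disk5`).
#'
#' @param path file path.
#' @return [read_events()]: data frame `label`, `time_s`.
#' @export
read_events <- function(path) {
  df <- .read_delim_checked(path, c("label", "time_s"))
  df$time_s <- as.numeric(df$time_s)
  if (anyNA(df$time_s)) stop("parse error in '", path, "': non-numeric time_s")
  df
}

#' @rdname read_events
#' @param events data frame with columns `label`, `time_s`.
#' @export
write_events <- function(events, path) {
  stopifnot(is.data.frame(events), all(c("label", "time_s") %in% names(events)))
  utils::write.csv(events[, c("label", "time_s")], path,
                   row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Serialize a stimulus train as an event file
#'
#' @param train a [loom_schedule()] result.
#' @param path file path.
#' @export
write_train <- function(train, path) {
  stopifnot(inherits(train, "stimulus_train"))
  write_events(data.frame(
    label = c("trigger", sprintf("disk%d", seq_along(train$disk_onsets))),
    time_s = c(train$trigger_time, train$disk_onsets)), path)
}

#' Write / read a corrected trace with a metadata header
#'
#' The metadata block (`# key: value` lines: fit coefficients, epoch
#' window) precedes the CSV columns `time`, `dff`, `z`.
#'
#' @param trace a [corrected_trace][isosbestic_correct()] (z stage optional).
#' @param path file path.
#' @export
write_corrected <- function(trace, path) {
  stopifnot(inherits(trace, "corrected_trace"))
  hdr <- c(sprintf("# fit_slope: %.17g", trace$fit_slope),
           sprintf("# fit_intercept: %.17g", trace$fit_intercept),
           sprintf("# sampling_rate: %.17g", trace$sampling_rate))
  if (!is.null(trace$epoch_window))
    hdr <- c(hdr, sprintf("# epoch_window: %.17g %.17g",
                          trace$epoch_window[1L], trace$epoch_window[2L]))
  con <- file(path, "w"); on.exit(close(con))
  writeLines(hdr, con)
  utils::write.csv(data.frame(time = trace$time, dff = trace$dff,
                              z = if (is.null(trace$z)) NA else trace$z),
                   con, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_corrected
#' @export
read_corrected <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- readLines(path)
  hdr <- grep("^#", lines, value = TRUE)
  meta <- list()
  for (h in hdr) {
    kv <- sub("^#\\s*", "", h)
    key <- sub(":.*$", "", kv)
    meta[[key]] <- as.numeric(strsplit(trimws(sub("^[^:]+:", "", kv)),
                                       "\\s+")[[1L]])
  }
  df <- utils::read.csv(textConnection(grep("^#", lines, value = TRUE,
                                            invert = TRUE)))
  structure(list(time = df$time, dff = df$dff,
                 z = if (all(is.na(df$z))) NULL else df$z,
                 fit_slope = meta$fit_slope, fit_intercept = meta$fit_intercept,
                 sampling_rate = meta$sampling_rate,
                 events = data.frame(label = character(), time_s = numeric()),
                 epoch_window = meta$epoch_window),
            class = "corrected_trace")
}

#' Write per-event peak or behavioral-bout tables as delimited text
#'
#' Plain CSV writers for the data frames produced by [detect_peaks()],
#' [detect_movement_bouts()] and [detect_freezing()].
#'
#' @param x a data frame.
#' @param path file path.
#' @export
write_table_csv <- function(x, path) {
  stopifnot(is.data.frame(x))
  utils::write.csv(x, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read / write the flat sectioned configuration format
#'
#' Plain text with `[section]` headers and `key = value` lines; numeric
#' and logical values are parsed, everything else stays character.
#'
#' @param path file path.
#' @return [read_config()]: named list of sections, each a named list.
#' @export
read_config <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  lines <- trimws(readLines(path))
  lines <- lines[nzchar(lines) & !startsWith(lines, "#")]
  out <- list(); section <- "default"
  for (ln in lines) {
    if (grepl("^\\[.*\\]$", ln)) {
      section <- gsub("^\\[|\\]$", "", ln)
      next
    }
    if (!grepl("=", ln)) stop("malformed config line: ", ln)
    key <- trimws(sub("=.*$", "", ln))
    val <- trimws(sub("^[^=]*=", "", ln))
    num <- suppressWarnings(as.numeric(val))
    parsed <- if (!is.na(num)) num
      else if (tolower(val) %in% c("true", "false")) as.logical(toupper(val))
      else val
    out[[section]][[key]] <- parsed
  }
  out
}

#' @rdname read_config
#' @param config named list of sections (e.g. [loom_config()]).
#' @export
write_config <- function(config, path) {
  con <- file(path, "w"); on.exit(close(con))
  for (section in names(config)) {
    writeLines(sprintf("[%s]", section), con)
    for (key in names(config[[section]])) {
      v <- config[[section]][[key]]
      writeLines(sprintf("%s = %s", key,
                         paste(format(v, digits = 17), collapse = " ")), con)
    }
    writeLines("", con)
  }
  invisible(path)
}

#' Write a ground-truth sidecar in structured text
#'
#' Flat `key = value` records (vectors space-separated) mirroring the
#' session ground truth; readable with [read_config()].
#'
#' @param truth a `session_ground_truth` list.
#' @param path file path.
#' @export
write_ground_truth <- function(truth, path) {
  flat <- function(x, prefix = "") {
    out <- list()
    for (nm in names(x)) {
      v <- x[[nm]]
      key <- if (nzchar(prefix)) paste0(prefix, ".", nm) else nm
      if (is.list(v) && !is.null(names(v))) {
        out <- c(out, flat(v, key))
      } else if (is.atomic(v) && length(v)) {
        out[[key]] <- v
      }
    }
    out
  }
  fields <- flat(truth[!vapply(truth, is.null, logical(1)) &
                         !names(truth) %in% "coupling"])
  write_config(list(ground_truth = fields), path)
}
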