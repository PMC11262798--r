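#' Continuous LFP signal
#'
#' Container for one recording site's local field potential: a numeric
#' sample vector with its sampling rate, anatomical region label and start
#' time. Voltages are conventionally in microvolts but the container does
#' not enforce a unit.
#'
#' @param samples Numeric vector of voltage samples.
#' @param sampling_rate Sampling rate in Hz (> 0). Nominal acquisition rate
#'   for this kind of recording is 2 kHz.
#' @param region Region label, one of `"mPFC"`, `"HPC"`, `"VMT"`, `"other"`.
#' @param start_time Time of the first sample, in seconds.
#' @return An object of class `continuous_signal`.
#' @export
continuous_signal <- function(samples, sampling_rate, region = "other",
                              start_time = 0) {
  if (!is.numeric(sampling_rate) || length(sampling_rate) != 1L ||
      !is.finite(sampling_rate) || sampling_rate <= 0) {
    stop("invalid sampling rate")
  }
  region <- match.arg(region, c("mPFC", "HPC", "VMT", "other"))
  samples <- as.numeric(samples)
  if (length(samples) < 1L) stop("signal must contain at least one sample")
  structure(
    list(samples = samples, sampling_rate = sampling_rate,
         region = region, start_time = as.numeric(start_time)),
    class = "continuous_signal"
  )
}

#' @export
print.continuous_signal <- function(x, ...) {
  dur <- length(x$samples) / x$sampling_rate
  cat(sprintf("<continuous_signal> %s: %d samples @ %g Hz (%.2f s from t=%g)\n",
              x$region, length(x$samples), x$sampling_rate, dur, x$start_time))
  invisible(x)
}

#' Signal duration in seconds
#' @param signal A `continuous_signal`.
#' @return Duration in seconds.
#' @export
signal_duration <- function(signal) {
  length(signal$samples) / signal$sampling_rate
}

#' Spike train
#'
#' Spike timestamps for one unit. Timestamps are deduplicated and sorted so
#' the stored vector is strictly increasing (repeated timestamps arise when
#' overlapping epochs are concatenated upstream and must be counted once).
#'
#' @param timestamps Spike times in seconds.
#' @param unit_id Unit label.
#' @param region Region label.
#' @return An object of class `spike_train`.
#' @export
spike_train <- function(timestamps, unit_id = "unit1", region = "other") {
  ts <- sort(unique(as.numeric(timestamps)))
  structure(list(timestamps = ts, unit_id = unit_id, region = region),
            class = "spike_train")
}

#' @export
print.spike_train <- function(x, ...) {
  cat(sprintf("<spike_train> %s (%s): %d spikes\n",
              x$unit_id, x$region, length(x$timestamps)))
  invisible(x)
}

EVENT_KINDS <- c("trial_start", "door_open", "beam_break", "choice_entry",
                 "choice_exit", "reward", "session_start")

#' Behavioral event log
#'
#' @param time Event times in seconds (non-decreasing after sorting).
#' @param kind Event kinds from the closed vocabulary: trial_start,
#'   door_open, beam_break, choice_entry, choice_exit, reward,
#'   session_start.
#' @param payload Optional character payload per event (e.g. "trial=3").
#' @return A data frame of class `event_log` with columns time, kind,
#'   payload, sorted by time (stable).
#' @export
event_log <- function(time = numeric(), kind = character(),
                      payload = character(length(time))) {
  kind <- as.character(kind)
  bad <- setdiff(unique(kind), EVENT_KINDS)
  if (length(bad)) stop("unknown event kind(s): ", paste(bad, collapse = ", "))
  if (length(payload) == 0L) payload <- character(length(time))
  df <- data.frame(time = as.numeric(time), kind = kind,
                   payload = as.character(payload),
                   stringsAsFactors = FALSE)
  df <- df[order(df$time), , drop = FALSE]
  rownames(df) <- NULL
  class(df) <- c("event_log", "data.frame")
  df
}

#' Position track
#'
#' 2-D position over time. Coordinates are in native tracking units unless
#' a `scale` (units per native unit, e.g. cm per pixel) is supplied, in
#' which case coordinates are interpreted as already scaled by the caller.
#'
#' @param x,y Coordinate vectors.
#' @param t Strictly increasing time vector (seconds), same length.
#' @param scale Optional numeric conversion factor carried as metadata.
#' @return An object of class `behavior_track`.
#' @export
behavior_track <- function(x, y, t, scale = NULL) {
  x <- as.numeric(x); y <- as.numeric(y); t <- as.numeric(t)
  if (length(x) != length(y) || length(x) != length(t)) {
    stop("x, y, t must have equal length")
  }
  if (length(t) > 1L && any(diff(t) <= 0)) stop("t must be strictly increasing")
  structure(list(x = x, y = y, t = t, scale = scale),
            class = "behavior_track")
}

#' @export
print.behavior_track <- function(x, ...) {
  cat(sprintf("<behavior_track> %d points over %.2f s\n",
              length(x$t), diff(range(x$t))))
  invisible(x)
}

# --- on-disk formats ---------------------------------------------------------
# Continuous signals: raw little-endian float64 sample block (<path>) plus a
# plain-text sidecar header (<path>.hdr) carrying sampling_rate, region,
# start_time. Spikes, events and tracks: tab-delimited text with a header
# row. A deliberately minimal open dialect; vendor formats are out of scope.

#' Write / read a continuous signal
#'
#' `write_signal()` stores the samples as a little-endian float64 block and
#' the metadata in a `<path>.hdr` sidecar text file; `read_signal()` inverts
#' it losslessly.
#'
#' @param signal A `continuous_signal`.
#' @param path File path for the sample block.
#' @return `read_signal()` returns the `continuous_signal`;
#'   `write_signal()` returns `path` invisibly.
#' @export
write_signal <- function(signal, path) {
  stopifnot(inherits(signal, "continuous_signal"))
  con <- file(path, "wb")
  on.exit(close(con))
  writeBin(signal$samples, con, size = 8, endian = "little")
  hdr <- c(
    sprintf("sampling_rate\t%.17g", signal$sampling_rate),
    sprintf("region\t%s", signal$region),
    sprintf("start_time\t%.17g", signal$start_time),
    sprintf("n_samples\t%d", length(signal$samples))
  )
  writeLines(hdr, paste0(path, ".hdr"))
  invisible(path)
}

#' @rdname write_signal
#' @export
read_signal <- function(path) {
  hdr_path <- paste0(path, ".hdr")
  if (!file.exists(path) || !file.exists(hdr_path)) {
    stop("signal file or header missing: ", path)
  }
  hdr <- utils::read.delim(hdr_path, header = FALSE,
                           col.names = c("key", "value"),
                           stringsAsFactors = FALSE)
  get <- function(k) hdr$value[match(k, hdr$key)]
  rate <- suppressWarnings(as.numeric(get("sampling_rate")))
  if (is.na(rate) || rate <= 0) stop("invalid sampling rate")
  n <- as.integer(get("n_samples"))
  con <- file(path, "rb")
  on.exit(close(con))
  samples <- readBin(con, "double", n = n, size = 8, endian = "little")
  continuous_signal(samples, rate, region = get("region"),
                    start_time = as.numeric(get("start_time")))
}

#' Write / read a spike train as delimited text
#' @param spikes A `spike_train`.
#' @param path File path.
#' @return `read_spikes()` returns a `spike_train`.
#' @export
write_spikes <- function(spikes, path) {
  df <- data.frame(timestamp = spikes$timestamps,
                   unit_id = spikes$unit_id, region = spikes$region)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_spikes
#' @export
read_spikes <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE)
  spike_train(df$timestamp, unit_id = df$unit_id[1], region = df$region[1])
}

#' Write / read an event log as delimited text
#' @param events An `event_log`.
#' @param path File path.
#' @return `read_events()` returns an `event_log`.
#' @export
write_events <- function(events, path) {
  utils::write.table(as.data.frame(events), path, sep = "\t",
                     row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_events
#' @export
read_events <- function(path) {
  df <- utils::read.delim(path, stringsAsFactors = FALSE,
                          colClasses = c("numeric", "character", "character"),
                          na.strings = NULL)
  event_log(df$time, df$kind, df$payload)
}

#' Write / read a position track as delimited text
#' @param track A `behavior_track`.
#' @param path File path.
#' @return `read_track()` returns a `behavior_track`.
#' @export
write_track <- function(track, path) {
  df <- data.frame(t = track$t, x = track$x, y = track$y)
  utils::write.table(df, path, sep = "\t", row.names = FALSE, quote = FALSE)
  attr_line <- if (!is.null(track$scale)) sprintf("# scale=%.17g", track$scale)
  if (!is.null(attr_line)) {
    txt <- readLines(path)
    writeLines(c(attr_line, txt), path)
  }
  invisible(path)
}

#' @rdname write_track
#' @export
read_track <- function(path) {
  first <- readLines(path, n = 1L)
  scale <- NULL
  skip <- 0L
  if (startsWith(first, "# scale=")) {
    scale <- as.numeric(sub("# scale=", "", first))
    skip <- 1L
  }
  df <- utils::read.delim(path, skip = skip, stringsAsFactors = FALSE)
  behavior_track(df$x, df$y, df$t, scale = scale)
}

#' Convert an event time to a sample index
#'
#' Rounds toward negative infinity (floor), the package-wide tie-breaking
#' convention, and returns a 1-based index into the sample vector.
#'
#' @param t Time in seconds.
#' @param signal A `continuous_signal`.
#' @return Integer sample index (may lie outside the record).
#' @export
time_to_index <- function(t, signal) {
  as.integer(floor((t - signal$start_time) * signal$sampling_rate)) + 1L
}

#' Extract event-locked epochs from a continuous signal
#'
#' Cuts one fixed-length sample block per matching event, time-locked to
#' the event, covering `window[1]` seconds before to `window[2]` seconds
#' after. Epochs are sample-index half-open intervals `[start, end)`;
#' events too close to either record edge are skipped and reported.
#'
#' @param signal A `continuous_signal`.
#' @param events An `event_log`.
#' @param kind Event kind to lock to (must be in the event vocabulary).
#' @param window Numeric `c(pre, post)` in seconds, both `>= 0`.
#' @return A list with `epochs` (list of numeric vectors, all the same
#'   length `round((pre + post) * rate)`), `event_times` (the event times
#'   used, in order), and `skipped` (times of events that fell off an
#'   edge).
#' @export
extract_epochs <- function(signal, events, kind, window) {
  if (!kind %in% EVENT_KINDS) stop("unknown event kind: ", kind)
  stopifnot(length(window) == 2L, all(window >= 0))
  fs <- signal$sampling_rate
  n_len <- as.integer(round(sum(window) * fs))
  times <- events$time[events$kind == kind]
  epochs <- list(); used <- numeric(); skipped <- numeric()
  n <- length(signal$samples)
  for (tt in times) {
    start <- time_to_index(tt - window[1], signal)
    stop_ <- start + n_len            # half-open [start, stop_)
    if (start < 1L || stop_ > n + 1L) {
      skipped <- c(skipped, tt)
    } else {
      epochs[[length(epochs) + 1L]] <- signal$samples[start:(stop_ - 1L)]
      used <- c(used, tt)
    }
  }
  list(epochs = epochs, event_times = used, skipped = skipped)
}
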