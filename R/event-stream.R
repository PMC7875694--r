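#' Durative sensor event streams
#'
#' An `event_stream` holds the time-ordered durative events recorded by one
#' sensor (call, battery charging, or screen unlock) for one participant,
#' together with the observation span over which the sensor was active.
#' Events carry only a start timestamp and a duration in seconds; no
#' identifying payload (numbers, contact names) is ever stored.
#'
#' @param participant_id Single string identifying the participant.
#' @param sensor One of `"call"`, `"battery"`, `"screen"`.
#' @param start `POSIXct` vector of event start times.
#' @param duration Numeric vector of event durations in seconds (all >= 0).
#' @param span Length-2 `POSIXct` observation span; defaults to
#'   `[min(start), max(start + duration)]`. Must have positive length when the
#'   stream is non-empty.
#' @param tz IANA timezone used for hour-of-day computations. Defaults to the
#'   timezone of `start`.
#'
#' @return An object of class `event_stream`: a list with elements
#'   `participant_id`, `sensor`, `events` (data frame with `start`,
#'   `duration`), `span`, and `tz`. Events are sorted ascending by start.
#' @export
event_stream <- function(participant_id, sensor, start, duration,
                         span = NULL, tz = NULL) {
  sensor <- match.arg(sensor, SENSORS)
  stopifnot(is.character(participant_id), length(participant_id) == 1L)
  if (length(start) != length(duration)) {
    stop("`start` and `duration` must have equal length")
  }
  if (!inherits(start, "POSIXct")) stop("`start` must be POSIXct")
  duration <- as.double(duration)
  if (anyNA(start)) stop("missing start timestamp at row ", which(is.na(start))[1])
  if (anyNA(duration) || any(duration < 0)) {
    bad <- which(is.na(duration) | duration < 0)[1]
    stop("invalid (negative or missing) duration at row ", bad)
  }
  tz <- tz %||% attr(start, "tzone") %||% "UTC"
  ord <- order(start, duration)
  start <- start[ord]
  duration <- duration[ord]
  if (is.null(span)) {
    span <- if (length(start)) {
      c(min(start), max(start + duration))
    } else {
      as.POSIXct(c(NA, NA), tz = tz)
    }
  }
  span <- as.POSIXct(span, tz = tz)
  if (length(span) != 2L) stop("`span` must have length 2")
  structure(
    list(
      participant_id = participant_id,
      sensor = sensor,
      events = data.frame(start = start, duration = duration),
      span = span,
      tz = tz
    ),
    class = "event_stream"
  )
}

#' @export
print.event_stream <- function(x, ...) {
  cat(sprintf(
    "<event_stream> %s / %s: %d events, span %s .. %s (%s)\n",
    x$participant_id, x$sensor, nrow(x$events),
    format(x$span[1]), format(x$span[2]), x$tz
  ))
  invisible(x)
}

n_events <- function(stream) nrow(stream$events)

#' Validate an event stream
#'
#' Checks the structural invariants: sorted events, non-negative durations,
#' every event start inside the observation span, and a positive-length span.
#'
#' @param stream An [event_stream].
#' @return `TRUE` invisibly; errors describe the first violated invariant.
#' @export
validate_event_stream <- function(stream) {
  stopifnot(inherits(stream, "event_stream"))
  ev <- stream$events
  if (anyNA(stream$span) || !(diff(as.double(stream$span)) > 0)) {
    stop("observation span is empty or has non-positive length")
  }
  if (nrow(ev)) {
    if (is.unsorted(ev$start)) stop("events are not sorted by start time")
    if (any(ev$duration < 0)) stop("negative event duration")
    if (any(ev$start < stream$span[1] | ev$start > stream$span[2])) {
      stop("event start outside the observation span")
    }
  }
  invisible(TRUE)
}

parse_iso8601 <- function(x, tz) {
  out <- as.POSIXct(rep(NA_real_, length(x)), origin = "1970-01-01", tz = tz)
  for (fmt in c("%Y-%m-%dT%H:%M:%OS", "%Y-%m-%d %H:%M:%OS",
                "%Y-%m-%dT%H:%M", "%Y-%m-%d")) {
    miss <- is.na(out)
    if (!any(miss)) break
    out[miss] <- as.POSIXct(strptime(x[miss], format = fmt, tz = tz), tz = tz)
  }
  out
}

#' Read a raw sensor event log
#'
#' Accepts the interchange CSV dialect
#' (`participant_id,sensor,start_iso8601,duration_s[,notification_flag]`,
#' header required) or JSON-lines with the same fields (one object per line,
#' detected from a `.jsonl`/`.ndjson` extension or a leading `{`). Rows whose
#' `notification_flag` is true are dropped: notification-induced screen-on
#' events are excluded upstream by the collector and the flag is honoured when
#' present. Events are sorted on read.
#'
#' @param path Path to the log file.
#' @param sensor Expected sensor kind; a mismatching `sensor` column is an
#'   error.
#' @param tz IANA timezone for timestamps and hour-of-day binning.
#' @param span Optional length-2 observation span (e.g. from a sidecar
#'   config); defaults to `[first event start, last event end]`.
#'
#' @return An [event_stream]. An empty file yields an empty stream whose span
#'   is flagged invalid by [validate_event_stream()].
#' @export
read_event_log <- function(path, sensor, tz = "UTC", span = NULL) {
  sensor <- match.arg(sensor, SENSORS)
  if (!file.exists(path)) stop("no such file: ", path)
  first <- readLines(path, n = 1L, warn = FALSE)
  jsonl <- grepl("\\.(jsonl|ndjson)$", path) ||
    (length(first) == 1L && startsWith(trimws(first), "{"))
  if (jsonl) {
    lines <- readLines(path, warn = FALSE)
    lines <- lines[nzchar(trimws(lines))]
    df <- if (length(lines)) {
      do.call(rbind, lapply(lines, function(l) {
        as.data.frame(jsonlite::fromJSON(l), stringsAsFactors = FALSE)
      }))
    } else NULL
  } else {
    df <- tryCatch(
      utils::read.csv(path, stringsAsFactors = FALSE, colClasses = "character"),
      error = function(e) NULL
    )
  }
  if (is.null(df) || nrow(df) == 0L) {
    return(event_stream("unknown", sensor, as.POSIXct(character(), tz = tz),
                        numeric(), span = span, tz = tz))
  }
  need <- c("participant_id", "sensor", "start_iso8601", "duration_s")
  if (!all(need %in% names(df))) {
    stop("log is missing required columns: ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  if (any(df$sensor != sensor)) {
    stop("sensor column disagrees with requested kind '", sensor, "'")
  }
  if ("notification_flag" %in% names(df)) {
    flag <- tolower(as.character(df$notification_flag)) %in%
      c("1", "true", "t", "yes")
    df <- df[!flag, , drop = FALSE]
  }
  start <- parse_iso8601(df$start_iso8601, tz)
  if (anyNA(start)) {
    stop("malformed timestamp at data row ", which(is.na(start))[1],
         ": '", df$start_iso8601[which(is.na(start))[1]], "'")
  }
  duration <- suppressWarnings(as.double(df$duration_s))
  if (anyNA(duration) || any(duration < 0)) {
    bad <- which(is.na(duration) | duration < 0)[1]
    stop("malformed or negative duration at data row ", bad,
         ": '", df$duration_s[bad], "'")
  }
  pid <- unique(df$participant_id)
  if (length(pid) != 1L) stop("log mixes multiple participants: ",
                              paste(pid, collapse = ", "))
  event_stream(pid, sensor, start, duration, span = span, tz = tz)
}

#' Write an event stream to the interchange CSV dialect
#'
#' @param stream An [event_stream].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_event_log <- function(stream, path) {
  stopifnot(inherits(stream, "event_stream"))
  df <- data.frame(
    participant_id = rep(stream$participant_id, n_events(stream)),
    sensor = rep(stream$sensor, n_events(stream)),
    start_iso8601 = format(stream$events$start, "%Y-%m-%dT%H:%M:%OS3",
                           tz = stream$tz),
    duration_s = format(stream$events$duration, scientific = FALSE, trim = TRUE)
  )
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

filter_stream <- function(stream, keep) {
  n0 <- n_events(stream)
  out <- stream
  out$events <- stream$events[keep, , drop = FALSE]
  rownames(out$events) <- NULL
  frac <- if (n0 == 0L) 0 else (n0 - sum(keep)) / n0
  list(stream = out, fraction_removed = frac)
}

#' Remove spurious short battery-charging events
#'
#' Cable jiggle and OS glitches produce ~1-second charging events; events
#' strictly shorter than `min_duration` seconds are dropped. A 10 s event
#' survives the default threshold.
#'
#' @param stream A battery [event_stream].
#' @param min_duration Threshold in seconds (default 10).
#' @return List with the filtered `stream` and `fraction_removed` (removed /
#'   original count; 0 for an empty stream).
#' @export
filter_battery <- function(stream, min_duration = 10) {
  stopifnot(inherits(stream, "event_stream"))
  if (stream$sensor != "battery") {
    stop("filter_battery() expects a battery stream, got '", stream$sensor, "'")
  }
  filter_stream(stream, stream$events$duration >= min_duration)
}

#' Remove over-long screen unlock sessions
#'
#' Sessions strictly longer than `max_duration` hours (default 2) are taken
#' to reflect unrelated continuous use (e.g. navigation) and dropped; a
#' session of exactly 2 hours survives.
#'
#' @param stream A screen [event_stream].
#' @param max_duration Threshold in hours (default 2).
#' @return List with the filtered `stream` and `fraction_removed`.
#' @export
filter_screen <- function(stream, max_duration = 2) {
  stopifnot(inherits(stream, "event_stream"))
  if (stream$sensor != "screen") {
    stop("filter_screen() expects a screen stream, got '", stream$sensor, "'")
  }
  filter_stream(stream, stream$events$duration <= max_duration * 3600)
}

#' Apply the sensor-appropriate cleaning filter
#'
#' Battery streams get the short-event filter, screen streams the long-session
#' filter; call streams pass through unchanged.
#'
#' @inheritParams filter_battery
#' @return List with `stream` and `fraction_removed`.
#' @export
clean_stream <- function(stream) {
  switch(stream$sensor,
    battery = filter_battery(stream),
    screen = filter_screen(stream),
    list(stream = stream, fraction_removed = 0)
  )
}
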