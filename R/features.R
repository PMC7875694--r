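#' Time windows
#'
#' A window is a half-open interval `[start, end)`: events belong to the
#' window when their start time lies inside it. Durations contributing to
#' usage are clipped to the window, so an unlock session straddling the edge
#' contributes only its in-window portion.
#'
#' @param start,end `POSIXct` endpoints with `end > start`.
#' @return Length-2 `POSIXct` vector of class `time_window`.
#' @export
time_window <- function(start, end) {
  w <- as.POSIXct(c(start, end))
  if (anyNA(w) || length(w) != 2L) stop("window needs two valid timestamps")
  if (!(as.double(w[2]) > as.double(w[1]))) stop("window must have end > start")
  class(w) <- c("time_window", class(w))
  w
}

as_window <- function(window) {
  if (inherits(window, "time_window")) return(window)
  time_window(window[1], window[2])
}

window_hours <- function(window) {
  as.double(difftime(window[2], window[1], units = "hours"))
}

in_window <- function(stream, window) {
  s <- as.double(stream$events$start)
  s >= as.double(window[1]) & s < as.double(window[2])
}

#' Usage per observed hour
#'
#' Total in-window event time, in hours, divided by the window length in
#' hours. Events straddling the window edge contribute only the clipped,
#' in-window portion of their duration; for that reason all events
#' overlapping the window are considered, not just those starting inside it.
#'
#' @param stream An [event_stream].
#' @param window A [time_window] (or length-2 `POSIXct`).
#' @return Dimensionless occupancy ratio (>= 0).
#' @export
use_per_hour <- function(stream, window) {
  window <- as_window(window)
  w1 <- as.double(window[1]); w2 <- as.double(window[2])
  s <- as.double(stream$events$start)
  e <- s + stream$events$duration
  lo <- pmax(s, w1)
  hi <- pmin(e, w2)
  occ <- sum(pmax(hi - lo, 0)) / 3600
  occ / window_hours(window)
}

#' Event frequency per observed hour
#'
#' @inheritParams use_per_hour
#' @return Count of events starting inside the window divided by the window
#'   length in hours.
#' @export
freq_per_hour <- function(stream, window) {
  window <- as_window(window)
  sum(in_window(stream, window)) / window_hours(window)
}

#' Duration mean and standard deviation
#'
#' Sample mean and SD of the durations (in hours) of events starting inside
#' the window. Full, unclipped durations are used: mean/SD characterise the
#' events themselves, while [use_per_hour()] characterises window occupancy.
#'
#' @inheritParams use_per_hour
#' @return Named numeric `c(mean =, sd =)` in hours. `(NA, NA)` with zero
#'   events; `(mean, 0)` with a single event.
#' @export
duration_moments <- function(stream, window) {
  window <- as_window(window)
  d <- stream$events$duration[in_window(stream, window)] / 3600
  if (length(d) == 0L) return(c(mean = NA_real_, sd = NA_real_))
  if (length(d) == 1L) return(c(mean = d, sd = 0))
  c(mean = mean(d), sd = stats::sd(d))
}

#' Hour-of-day occurrence entropy
#'
#' Shannon entropy of the distribution of event start times over the 24
#' hour-of-day bins (participant-local clock). Uniform activity across the
#' day gives the maximum `log(24)` (~3.178 nats); activity concentrated in a
#' single clock hour gives 0. Durations are ignored: the statistic reflects
#' *when* events occur, not for how long.
#'
#' @inheritParams use_per_hour
#' @param base Logarithm base; the default `exp(1)` reports nats.
#' @return Entropy in `[0, log(24, base)]`, or `NA` for an event-free window.
#' @export
occurrence_entropy <- function(stream, window, base = exp(1)) {
  window <- as_window(window)
  st <- stream$events$start[in_window(stream, window)]
  if (length(st) == 0L) return(NA_real_)
  hr <- as.POSIXlt(st, tz = stream$tz)$hour
  p <- tabulate(hr + 1L, nbins = 24L) / length(hr)
  p <- p[p > 0]
  -sum(p * log(p, base = base))
}

#' Assemble the 15 passive features for one participant-window
#'
#' For each of the three sensors, computes usage per hour, frequency per
#' hour, duration mean and SD (hours), and hour-of-day occurrence entropy
#' (nats). A sensor absent from `streams` yields `NA` in its five slots with
#' a warning. Use and Freq are genuinely 0 for an event-free window; Mean,
#' SD and Ent are `NA` there because their defining event set is empty.
#'
#' @param streams Named list of [event_stream]s for one participant; names
#'   (or `$sensor` fields) identify the sensor kinds.
#' @param window A [time_window].
#' @param entropy_base Log base for [occurrence_entropy()].
#' @return Named numeric vector of length 15 in [feature_names()] order.
#' @export
extract_features <- function(streams, window, entropy_base = exp(1)) {
  window <- as_window(window)
  by_sensor <- list()
  for (s in streams) by_sensor[[s$sensor]] <- s
  out <- stats::setNames(rep(NA_real_, 15L), feature_names())
  absent <- setdiff(c("battery", "call", "screen"), names(by_sensor))
  if (length(absent)) {
    warning("no ", paste(absent, collapse = "/"),
            " stream supplied; those features are missing")
  }
  for (sensor in c("battery", "call", "screen")) {
    st <- by_sensor[[sensor]]
    if (is.null(st)) next
    m <- duration_moments(st, window)
    out[paste0(sensor, "_Use")] <- use_per_hour(st, window)
    out[paste0(sensor, "_Freq")] <- freq_per_hour(st, window)
    out[paste0(sensor, "_Mean")] <- m[["mean"]]
    out[paste0(sensor, "_SD")] <- m[["sd"]]
    out[paste0(sensor, "_Ent")] <- occurrence_entropy(st, window,
                                                      base = entropy_base)
  }
  out
}

#' 24-hour windows preceding morning assessments
#'
#' Daily-state analyses pair each morning assessment at time `t` with the
#' sensor window `[t - 24 h, t)`. Irregular assessment times may produce
#' overlapping windows; they are returned as-is.
#'
#' @param assessment_times Sorted `POSIXct` assessment timestamps for one
#'   participant; duplicates are an error.
#' @return List of [time_window]s, one per assessment.
#' @export
daily_windows <- function(assessment_times) {
  if (anyDuplicated(assessment_times)) {
    stop("duplicate assessment timestamps")
  }
  assessment_times <- sort(assessment_times)
  lapply(seq_along(assessment_times), function(i) {
    t <- assessment_times[i]
    time_window(t - 24 * 3600, t)
  })
}

#' Trait-level feature table for a cohort
#'
#' One row per participant: the 15 features computed over each participant's
#' full observation span (cleaned streams).
#'
#' @param cohort_streams Named list (by participant id) of lists of cleaned
#'   [event_stream]s.
#' @param entropy_base Log base for entropy.
#' @return Data frame with `participant_id` plus the 15 feature columns.
#' @export
trait_features <- function(cohort_streams, entropy_base = exp(1)) {
  rows <- lapply(names(cohort_streams), function(pid) {
    streams <- cohort_streams[[pid]]
    spans <- do.call(rbind, lapply(streams, function(s) as.double(s$span)))
    window <- time_window(
      as.POSIXct(min(spans[, 1]), origin = "1970-01-01", tz = streams[[1]]$tz),
      as.POSIXct(max(spans[, 2]), origin = "1970-01-01", tz = streams[[1]]$tz)
    )
    c(extract_features(streams, window, entropy_base = entropy_base))
  })
  out <- as.data.frame(do.call(rbind, rows))
  cbind(participant_id = names(cohort_streams), out)
}

#' Daily feature table for a cohort
#'
#' One row per participant-day: the 15 features over the 24-hour window
#' preceding that day's morning assessment.
#'
#' @param cohort_streams Named list (by participant id) of lists of cleaned
#'   [event_stream]s.
#' @param assessments Data frame with `participant_id` and POSIXct
#'   `morning_time` columns.
#' @param entropy_base Log base for entropy.
#' @return Data frame with `participant_id`, `morning_time`, and the 15
#'   feature columns.
#' @export
daily_features <- function(cohort_streams, assessments, entropy_base = exp(1)) {
  out <- list()
  for (pid in unique(assessments$participant_id)) {
    streams <- cohort_streams[[pid]]
    if (is.null(streams)) next
    times <- assessments$morning_time[assessments$participant_id == pid]
    wins <- daily_windows(times)
    feats <- do.call(rbind, lapply(wins, function(w) {
      extract_features(streams, w, entropy_base = entropy_base)
    }))
    out[[pid]] <- cbind(
      data.frame(participant_id = pid, morning_time = sort(times)),
      as.data.frame(feats)
    )
  }
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
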