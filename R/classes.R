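#' Photometry trace
#'
#' A single excitation channel's fluorescence time series, either in raw
#' camera units or as zdF/F after correction. Stored as a data frame with
#' columns `time_s` and `value` plus channel/ROI metadata attributes.
#'
#' @param time_s Numeric vector of timestamps in seconds, strictly increasing.
#' @param value Numeric vector of fluorescence values, same length as `time_s`.
#' @param channel Excitation wavelength tag, e.g. `"415"` or `"470"`.
#' @param roi Fiber / region-of-interest tag.
#' @param rate_hz Nominal sampling rate in Hz. Estimated from the median
#'   inter-sample interval when `NULL`. The median interval must agree with
#'   `1/rate_hz` within 20%.
#' @param units Either `"camera"` (raw fluorescence) or `"zdff"`.
#' @return A `photometry_trace` object (data frame with attributes).
#' @export
photometry_trace <- function(time_s, value, channel = "470", roi = "Region0",
                             rate_hz = NULL, units = "camera") {
  if (length(time_s) != length(value))
    ff_stop("ff_data_error", "time_s and value lengths differ (%d vs %d)",
            length(time_s), length(value))
  if (length(time_s) < 2L)
    ff_stop("ff_data_error", "a trace needs at least 2 samples")
  dt <- diff(time_s)
  if (any(dt <= 0)) {
    i <- which(dt <= 0)[1L]
    ff_stop("ff_data_error",
            "timestamps must be strictly increasing (violation at sample %d)",
            i + 1L)
  }
  med_dt <- stats::median(dt)
  if (is.null(rate_hz)) rate_hz <- 1 / med_dt
  check_scalar(rate_hz, "rate_hz", lower = 0, strict_lower = TRUE)
  if (abs(med_dt - 1 / rate_hz) > 0.2 / rate_hz)
    ff_stop("ff_data_error",
            "median inter-sample interval %.4g s is not within 20%% of 1/rate (%.4g s)",
            med_dt, 1 / rate_hz)
  structure(
    data.frame(time_s = as.numeric(time_s), value = as.numeric(value)),
    channel = as.character(channel), roi = as.character(roi),
    rate_hz = rate_hz, units = units,
    class = c("photometry_trace", "data.frame")
  )
}

#' @export
print.photometry_trace <- function(x, ...) {
  cat(sprintf("<photometry_trace> channel %s, roi %s, %d samples @ %.3g Hz [%s]\n",
              attr(x, "channel"), attr(x, "roi"), nrow(x),
              attr(x, "rate_hz"), attr(x, "units")))
  cat(sprintf("  time %.3f .. %.3f s, value range [%.4g, %.4g]\n",
              x$time_s[1L], x$time_s[nrow(x)], min(x$value), max(x$value)))
  invisible(x)
}

trace_rate <- function(trace) attr(trace, "rate_hz")

#' Behavior track
#'
#' A mobility-score time series in `[0, 1]` (session-wise min-max normalized
#' speed), optionally carrying the raw speed it was derived from.
#'
#' @param time_s Timestamps in seconds, strictly increasing.
#' @param mobility Mobility score in `[0, 1]`, same length as `time_s`.
#' @param raw_speed Optional raw speed (length units / s).
#' @param rate_hz Nominal sampling rate; estimated when `NULL`.
#' @param degenerate Flag set when the source speed was constant and the
#'   min-max scaling was undefined (all-zero scores).
#' @return A `behavior_track` object (data frame with attributes).
#' @export
behavior_track <- function(time_s, mobility, raw_speed = NULL, rate_hz = NULL,
                           degenerate = FALSE) {
  if (length(time_s) != length(mobility))
    ff_stop("ff_data_error", "time_s and mobility lengths differ")
  if (any(diff(time_s) <= 0))
    ff_stop("ff_data_error", "timestamps must be strictly increasing")
  if (any(mobility < -1e-12 | mobility > 1 + 1e-12))
    ff_stop("ff_data_error", "mobility scores must lie in [0, 1]")
  if (is.null(rate_hz)) rate_hz <- 1 / stats::median(diff(time_s))
  df <- data.frame(time_s = as.numeric(time_s),
                   mobility = pmin(1, pmax(0, as.numeric(mobility))))
  if (!is.null(raw_speed)) df$raw_speed <- as.numeric(raw_speed)
  structure(df, rate_hz = rate_hz, degenerate = isTRUE(degenerate),
            class = c("behavior_track", "data.frame"))
}

#' @export
print.behavior_track <- function(x, ...) {
  cat(sprintf("<behavior_track> %d samples @ %.3g Hz, mobility [%.3f, %.3f]%s\n",
              nrow(x), attr(x, "rate_hz"), min(x$mobility), max(x$mobility),
              if (attr(x, "degenerate")) " (degenerate)" else ""))
  invisible(x)
}

#' Event series
#'
#' Labeled point events (times) or intervals (start/end pairs): licks, laser
#' epochs, CS times, bout onsets, chamber occupancy and the like.
#'
#' @param times_s For point events: sorted numeric event times.
#' @param start_s,end_s For interval events: sorted, non-overlapping interval
#'   bounds with `end_s > start_s`.
#' @param label Free tag, e.g. `"lick"`, `"consumption"`, `"laser"`.
#' @return An `event_series` object (data frame with attributes `label` and
#'   `type`, one of `"point"` or `"interval"`).
#' @export
event_series <- function(times_s = NULL, start_s = NULL, end_s = NULL,
                         label = "event") {
  if (!is.null(times_s)) {
    if (!is.null(start_s) || !is.null(end_s))
      ff_stop("ff_param_error", "give either times_s or start_s/end_s, not both")
    times_s <- as.numeric(times_s)
    if (is.unsorted(times_s)) times_s <- sort(times_s)
    df <- data.frame(time_s = times_s)
    type <- "point"
  } else {
    start_s <- as.numeric(start_s %||% numeric(0))
    end_s <- as.numeric(end_s %||% numeric(0))
    if (length(start_s) != length(end_s))
      ff_stop("ff_data_error", "start_s and end_s lengths differ")
    o <- order(start_s)
    start_s <- start_s[o]; end_s <- end_s[o]
    if (any(end_s <= start_s))
      ff_stop("ff_data_error", "intervals must have end_s > start_s")
    if (length(start_s) > 1L && any(start_s[-1L] < end_s[-length(end_s)]))
      ff_stop("ff_data_error", "intervals must not overlap")
    df <- data.frame(start_s = start_s, end_s = end_s)
    type <- "interval"
  }
  structure(df, label = as.character(label), type = type,
            class = c("event_series", "data.frame"))
}

#' @export
print.event_series <- function(x, ...) {
  cat(sprintf("<event_series> '%s': %d %s events\n",
              attr(x, "label"), nrow(x), attr(x, "type")))
  invisible(x)
}

event_times <- function(ev) {
  if (attr(ev, "type") == "point") ev$time_s else ev$start_s
}

interval_durations <- function(ev) {
  if (attr(ev, "type") != "interval")
    ff_stop("ff_data_error", "'%s' is not an interval series", attr(ev, "label"))
  ev$end_s - ev$start_s
}
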