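#' Interleaved multi-LED recording
#'
#' Raw camera frames before deinterleaving: a frame counter, timestamps, the
#' per-frame LED-state code, and one fluorescence column per ROI.
#'
#' @param frame_index Integer frame counter.
#' @param timestamp_s Strictly increasing timestamps (s).
#' @param led_state Integer LED-state code per frame (bitmask: 1 first
#'   channel, 2 second, 4 third).
#' @param values Data frame of per-frame fluorescence, one column per ROI.
#' @param channel_map Named character vector mapping code to channel label,
#'   e.g. `c("1" = "415", "2" = "470")`.
#' @return An `interleaved_recording` object.
#' @export
interleaved_recording <- function(frame_index, timestamp_s, led_state, values,
                                  channel_map) {
  n <- length(frame_index)
  if (length(timestamp_s) != n || length(led_state) != n || nrow(values) != n)
    ff_stop("ff_data_error", "frame_index, timestamp_s, led_state and values must have equal lengths")
  dt <- diff(timestamp_s)
  if (any(dt <= 0)) {
    i <- which(dt <= 0)[1L]
    ff_stop("ff_data_error",
            "timestamps not strictly increasing at row %d", i + 1L)
  }
  known <- as.integer(names(channel_map))
  unknown <- setdiff(unique(led_state), known)
  if (length(unknown))
    ff_warn("ff_unknown_code_warning",
            "unknown LED-state codes present: %s",
            paste(unknown, collapse = ", "))
  structure(list(
    frame_index = as.integer(frame_index),
    timestamp_s = as.numeric(timestamp_s),
    led_state = as.integer(led_state),
    values = as.data.frame(values),
    channel_map = channel_map
  ), class = "interleaved_recording")
}

#' @export
print.interleaved_recording <- function(x, ...) {
  cat(sprintf("<interleaved_recording> %d frames, %d ROI(s), codes {%s}\n",
              length(x$frame_index), ncol(x$values),
              paste(sort(unique(x$led_state)), collapse = ",")))
  invisible(x)
}

#' Read an interleaved frame table from CSV
#'
#' Expects the acquisition dialect: comma-separated with a header containing
#' `FrameCounter`, `Timestamp`, `LedState` and at least one region column
#' (any other column name is treated as an ROI).
#'
#' @param source Path to a CSV file or a connection.
#' @param channel_map Named character vector mapping LED-state code to
#'   channel label.
#' @return An [interleaved_recording()].
#' @export
read_frames <- function(source, channel_map) {
  df <- utils::read.csv(source, check.names = FALSE,
                        colClasses = NA, stringsAsFactors = FALSE)
  required <- c("FrameCounter", "Timestamp", "LedState")
  missing <- setdiff(required, names(df))
  if (length(missing))
    ff_stop("ff_format_error", "missing required column(s): %s",
            paste(missing, collapse = ", "))
  region_cols <- setdiff(names(df), required)
  if (!length(region_cols))
    ff_stop("ff_format_error", "no region (ROI) columns found")
  interleaved_recording(df$FrameCounter, df$Timestamp, df$LedState,
                        df[region_cols], channel_map)
}

#' Write an interleaved recording as CSV
#'
#' @param rec An [interleaved_recording()].
#' @param path Output CSV path.
#' @export
write_frames <- function(rec, path) {
  df <- data.frame(FrameCounter = rec$frame_index,
                   Timestamp = rec$timestamp_s,
                   LedState = rec$led_state,
                   check.names = FALSE)
  df <- cbind(df, rec$values)
  write_table_deterministic(df, path)
  invisible(path)
}

#' Deinterleave a recording into per-channel traces
#'
#' Splits frames by LED-state code into one [photometry_trace()] per
#' (channel, ROI). The per-trace nominal rate is the camera rate (estimated
#' from the timestamps) divided by the number of active channels. Frames
#' before the first complete LED cycle are kept; no frame is dropped.
#'
#' @param rec An [interleaved_recording()].
#' @return A named list `traces[[channel]][[roi]]` of photometry traces.
#' @export
deinterleave <- function(rec) {
  codes <- sort(unique(rec$led_state))
  n_active <- length(codes)
  camera_rate <- 1 / stats::median(diff(rec$timestamp_s))
  rate <- camera_rate / n_active
  out <- list()
  for (code in codes) {
    label <- rec$channel_map[[as.character(code)]] %||% as.character(code)
    sel <- rec$led_state == code
    if (sum(sel) < 2L)
      ff_stop("ff_data_error",
              "channel code %d has fewer than 2 frames", code)
    out[[label]] <- lapply(stats::setNames(nm = names(rec$values)), function(roi)
      photometry_trace(rec$timestamp_s[sel], rec$values[[roi]][sel],
                       channel = label, roi = roi, rate_hz = rate))
  }
  out
}

## --- session store -------------------------------------------------------
## A hierarchical on-disk container: a directory holding one CSV per named
## group plus a JSON manifest recording the layout version and per-group
## type/attribute metadata, so round-trips restore the original classes.

STORE_LAYOUT_VERSION <- "1"

serialize_group <- function(obj) {
  if (inherits(obj, "photometry_trace")) {
    list(type = "photometry_trace",
         attrs = list(channel = attr(obj, "channel"), roi = attr(obj, "roi"),
                      rate_hz = attr(obj, "rate_hz"), units = attr(obj, "units")),
         data = as.data.frame(obj))
  } else if (inherits(obj, "behavior_track")) {
    list(type = "behavior_track",
         attrs = list(rate_hz = attr(obj, "rate_hz"),
                      degenerate = attr(obj, "degenerate")),
         data = as.data.frame(obj))
  } else if (inherits(obj, "event_series")) {
    list(type = "event_series",
         attrs = list(label = attr(obj, "label"), type = attr(obj, "type")),
         data = as.data.frame(obj))
  } else if (is.data.frame(obj)) {
    list(type = "data.frame", attrs = list(), data = obj)
  } else if (is.numeric(obj) && is.null(dim(obj))) {
    list(type = "numeric", attrs = list(),
         data = data.frame(value = as.numeric(obj)))
  } else {
    ff_stop("ff_param_error", "unsupported group object of class '%s'",
            paste(class(obj), collapse = "/"))
  }
}

deserialize_group <- function(entry, df) {
  a <- entry$attrs
  switch(entry$type,
    photometry_trace = photometry_trace(df$time_s, df$value,
                                        channel = a$channel, roi = a$roi,
                                        rate_hz = a$rate_hz, units = a$units),
    behavior_track = behavior_track(df$time_s, df$mobility,
                                    raw_speed = df$raw_speed,
                                    rate_hz = a$rate_hz,
                                    degenerate = isTRUE(a$degenerate)),
    event_series = if (a$type == "point")
        event_series(times_s = df$time_s, label = a$label)
      else event_series(start_s = df$start_s, end_s = df$end_s,
                        label = a$label),
    data.frame = df,
    numeric = df$value,
    ff_stop("ff_format_error", "unknown stored type '%s'", entry$type)
  )
}

#' Store a session as named groups
#'
#' Writes a flat set of named groups (traces, tracks, event series, tables,
#' numeric vectors) into a directory-backed hierarchical store: one CSV per
#' group plus a JSON manifest with the layout version and metadata needed to
#' restore each object's class on load. Round-trips are numerically
#' identical to the written precision and byte-identical across reruns.
#'
#' @param path Store directory (created if needed; an existing manifest is
#'   overwritten).
#' @param groups Named list of storable objects; names may use `/` to
#'   express hierarchy (e.g. `"traces/470/Region0"`).
#' @export
store_session <- function(path, groups) {
  if (is.null(names(groups)) || any(names(groups) == ""))
    ff_stop("ff_param_error", "all groups must be named")
  dir.create(path, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(layout_version = STORE_LAYOUT_VERSION, groups = list())
  for (nm in names(groups)) {
    ser <- serialize_group(groups[[nm]])
    fname <- paste0(gsub("/", "__", nm), ".csv")
    write_table_deterministic(ser$data, file.path(path, fname))
    manifest$groups[[nm]] <- list(type = ser$type, file = fname,
                                  attrs = ser$attrs)
  }
  jsonlite::write_json(manifest, file.path(path, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}

#' Load a stored session
#'
#' @param path Store directory written by [store_session()].
#' @return A named list of restored groups, of class `session_store`.
#' @export
load_session <- function(path) {
  mpath <- file.path(path, "manifest.json")
  if (!file.exists(mpath))
    ff_stop("ff_format_error", "no manifest.json under '%s'", path)
  manifest <- jsonlite::read_json(mpath, simplifyVector = FALSE)
  if (is.null(manifest$layout_version))
    ff_stop("ff_version_error", "store at '%s' lacks a layout version", path)
  if (!identical(as.character(manifest$layout_version), STORE_LAYOUT_VERSION))
    ff_stop("ff_version_error", "unsupported layout version '%s'",
            manifest$layout_version)
  out <- list()
  for (nm in names(manifest$groups)) {
    entry <- manifest$groups[[nm]]
    df <- utils::read.csv(file.path(path, entry$file), check.names = FALSE)
    out[[nm]] <- deserialize_group(entry, df)
  }
  structure(out, class = c("session_store", "list"))
}

#' Retrieve one group from a loaded session
#'
#' @param session A `session_store` from [load_session()].
#' @param name Group name.
#' @return The stored object; a key error if the group is absent.
#' @export
get_group <- function(session, name) {
  if (!name %in% names(session))
    ff_stop("ff_key_error", "no group named '%s' in the session store", name)
  session[[name]]
}
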