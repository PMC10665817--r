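#' Speed from tracked coordinates
#'
#' Two-point speed: `sqrt((x1-x0)^2 + (y1-y0)^2) / (t1-t0)`, assigned to the
#' end time of each interval.
#'
#' @param x,y Coordinate vectors (equal length >= 2).
#' @param t Strictly increasing timestamps, same length.
#' @return Numeric vector of length `n - 1` of non-negative speeds, with the
#'   interval end times in attribute `"time_s"`.
#' @export
speed_from_coords <- function(x, y, t) {
  n <- length(t)
  if (length(x) != n || length(y) != n)
    ff_stop("ff_data_error", "x, y and t must have equal lengths")
  if (n < 2L) ff_stop("ff_data_error", "need at least 2 samples")
  dt <- diff(t)
  if (any(dt == 0)) {
    i <- which(dt == 0)[1L]
    ff_stop("ff_data_error", "repeated timestamp at sample %d", i + 1L)
  }
  if (any(dt < 0))
    ff_stop("ff_data_error", "timestamps must be increasing")
  sp <- sqrt(diff(x)^2 + diff(y)^2) / dt
  structure(sp, time_s = t[-1L])
}

#' Mobility score from speed
#'
#' Session-wise min-max normalization of speed to `[0, 1]`:
#' `(v - min) / (max - min)`. A constant speed has no defined scaling and
#' yields all zeros with the track flagged degenerate.
#'
#' @param speed Numeric speed vector (length >= 2).
#' @param time_s Optional timestamps; taken from `attr(speed, "time_s")` or
#'   defaulting to a unit-spaced grid.
#' @return A [behavior_track()].
#' @export
mobility_score <- function(speed, time_s = NULL) {
  if (length(speed) < 2L)
    ff_stop("ff_data_error", "need at least 2 speed samples")
  time_s <- time_s %||% attr(speed, "time_s") %||% (seq_along(speed) - 1)
  rng <- range(speed)
  if (diff(rng) == 0) {
    return(behavior_track(time_s, rep(0, length(speed)), raw_speed = speed,
                          degenerate = TRUE))
  }
  behavior_track(time_s, (speed - rng[1L]) / diff(rng), raw_speed = speed)
}

#' Segment a mobility track into immobility and mobility bouts
#'
#' An immobility bout is a maximal run of samples with mobility strictly
#' below `immobility_thresh` lasting at least `min_immobile_s` (a run's
#' duration spans from its first sub-threshold sample to the first
#' supra-threshold sample after it, or the session end). Mobility bouts are
#' the complement, so the two labels tile the session.
#'
#' @param track A [behavior_track()].
#' @param immobility_thresh Score threshold (strict `<`; samples equal to
#'   the threshold count as mobile).
#' @param min_immobile_s Minimum immobility duration in seconds.
#' @return A `bout_table`: data frame of `(start_s, end_s, label)` sorted,
#'   non-overlapping, tiling the session.
#' @export
detect_bouts <- function(track, immobility_thresh = 0.1, min_immobile_s = 2.0) {
  t <- track$time_s
  below <- track$mobility < immobility_thresh
  n <- length(t)
  t0 <- t[1L]; t_end <- t[n]
  r <- rle(below)
  idx_end <- cumsum(r$lengths)
  idx_start <- idx_end - r$lengths + 1L
  imm_start <- imm_end <- numeric(0)
  for (j in seq_along(r$values)) {
    if (!r$values[j]) next
    s <- t[idx_start[j]]
    e <- if (idx_end[j] < n) t[idx_end[j] + 1L] else t_end
    if (e - s >= min_immobile_s) {
      imm_start <- c(imm_start, s)
      imm_end <- c(imm_end, e)
    }
  }
  # mobility bouts: complement within [t0, t_end]
  mob_start <- mob_end <- numeric(0)
  cur <- t0
  for (j in seq_along(imm_start)) {
    if (imm_start[j] > cur) {
      mob_start <- c(mob_start, cur)
      mob_end <- c(mob_end, imm_start[j])
    }
    cur <- imm_end[j]
  }
  if (cur < t_end) {
    mob_start <- c(mob_start, cur)
    mob_end <- c(mob_end, t_end)
  }
  out <- rbind(
    data.frame(start_s = imm_start, end_s = imm_end,
               label = rep("immobility", length(imm_start))),
    data.frame(start_s = mob_start, end_s = mob_end,
               label = rep("mobility", length(mob_start)))
  )
  out <- out[order(out$start_s), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, session_start_s = t0, session_end_s = t_end,
            class = c("bout_table", "data.frame"))
}

#' Detect consumption events from lick contacts
#'
#' Contacts separated by gaps shorter than `max_gap_s` are merged into one
#' event; merged events whose total span is shorter than `min_event_s` are
#' discarded. The event onset is the first contact's start and the offset
#' the last contact's end (a consumption event ends once licks are absent
#' for `max_gap_s`).
#'
#' @param licks An interval [event_series()] of lick contacts (sorted,
#'   non-overlapping; sorting is enforced).
#' @param min_event_s Minimum merged-event duration (s).
#' @param max_gap_s Gap (s) at or above which an event ends.
#' @return An interval [event_series()] labeled `"consumption"`.
#' @export
detect_consumption <- function(licks, min_event_s = 0.5, max_gap_s = 1.0) {
  if (attr(licks, "type") != "interval")
    ff_stop("ff_data_error", "licks must be an interval event series")
  if (nrow(licks) == 0L)
    return(event_series(start_s = numeric(0), end_s = numeric(0),
                        label = "consumption"))
  o <- order(licks$start_s)
  on <- licks$start_s[o]; off <- licks$end_s[o]
  if (length(on) > 1L && any(on[-1L] < off[-length(off)]))
    ff_stop("ff_data_error", "lick contacts overlap")
  ev_on <- on[1L]; ev_off <- off[1L]
  out_on <- out_off <- numeric(0)
  for (i in seq_along(on)[-1L]) {
    if (on[i] - ev_off < max_gap_s) {
      ev_off <- off[i]
    } else {
      out_on <- c(out_on, ev_on); out_off <- c(out_off, ev_off)
      ev_on <- on[i]; ev_off <- off[i]
    }
  }
  out_on <- c(out_on, ev_on); out_off <- c(out_off, ev_off)
  keep <- (out_off - out_on) >= min_event_s
  event_series(start_s = out_on[keep], end_s = out_off[keep],
               label = "consumption")
}

#' Select peri-event analysis events from a bout table
#'
#' The four event kinds of the peri-event correlation analysis: mobility
#' onsets and immobility onsets (interior bout boundaries), and random times
#' drawn uniformly within mobility / immobility bouts with at least
#' `window_s / 2` clearance from bout edges and session edges so every
#' peri-event trace is complete.
#'
#' @param bouts A `bout_table` from [detect_bouts()].
#' @param kinds Subset of `c("mobility_onset", "immobility_onset",
#'   "random_mobility", "random_immobility")`.
#' @param n_random Number of random events per random kind.
#' @param window_s Peri-event window length (s) used for clearance.
#' @param seed Optional seed for the random draws.
#' @return Named list of point [event_series()], one per requested kind;
#'   kinds with no eligible bout yield an empty series with a warning.
#' @export
select_events <- function(bouts,
                          kinds = c("mobility_onset", "immobility_onset",
                                    "random_mobility", "random_immobility"),
                          n_random = 10L, window_s = 6.0, seed = NULL) {
  kinds <- match.arg(kinds, several.ok = TRUE)
  t0 <- attr(bouts, "session_start_s")
  t1 <- attr(bouts, "session_end_s")
  half <- window_s / 2
  onset_of <- function(label) {
    s <- bouts$start_s[bouts$label == label]
    s[s > t0]  # a bout starting with the session has no observed onset
  }
  draw_random <- function(label) {
    b <- bouts[bouts$label == label, , drop = FALSE]
    lo <- pmax(b$start_s + half, t0 + half)
    hi <- pmin(b$end_s - half, t1 - half)
    ok <- hi > lo
    if (!any(ok)) {
      ff_warn("ff_no_eligible_bout_warning",
              "no %s bout can hold a %g-s window; returning empty series",
              label, window_s)
      return(numeric(0))
    }
    lo <- lo[ok]; hi <- hi[ok]
    len <- hi - lo
    # draw bouts proportional to eligible span, then uniform within
    bsel <- sample.int(length(lo), n_random, replace = TRUE,
                       prob = len / sum(len))
    sort(lo[bsel] + stats::runif(n_random) * len[bsel])
  }
  with_local_seed(seed, {
    out <- list()
    for (k in kinds) {
      times <- switch(k,
        mobility_onset = onset_of("mobility"),
        immobility_onset = onset_of("immobility"),
        random_mobility = draw_random("mobility"),
        random_immobility = draw_random("immobility"))
      out[[k]] <- event_series(times_s = times, label = k)
    }
    out
  })
}

#' Read an ANY-maze-style state export
#'
#' A CSV with a time column and a 0/1 state column (lick contact, laser,
#' chamber occupancy); rising/falling edges delimit intervals. A final open
#' interval is closed at the last timestamp.
#'
#' @param path CSV path.
#' @param time_col,state_col Column names.
#' @param label Label for the resulting series.
#' @return An interval [event_series()].
#' @export
read_anymaze_events <- function(path, time_col = "Time", state_col = "State",
                                label = state_col) {
  df <- utils::read.csv(path, check.names = FALSE)
  for (col in c(time_col, state_col))
    if (!col %in% names(df))
      ff_stop("ff_format_error", "missing column '%s'", col)
  t <- df[[time_col]]
  s <- as.integer(df[[state_col]] > 0)
  edges <- diff(c(0L, s))
  on <- t[edges == 1L]
  off <- t[edges == -1L]
  if (length(off) < length(on)) off <- c(off, t[length(t)])
  event_series(start_s = on, end_s = off, label = label)
}

#' Read a DeepLabCut-style coordinate export
#'
#' DeepLabCut CSVs carry three header rows (scorer, bodyparts, coords);
#' this reader returns the x/y columns of one body part with the frame
#' times.
#'
#' @param path CSV path.
#' @param bodypart Body part name; defaults to the first one found.
#' @param rate_hz Frame rate used to build timestamps when the file has no
#'   time column (default 20).
#' @return Data frame with `time_s`, `x`, `y` (and `likelihood` if present).
#' @export
read_dlc_coords <- function(path, bodypart = NULL, rate_hz = 20) {
  hdr <- utils::read.csv(path, header = FALSE, nrows = 3,
                         check.names = FALSE, stringsAsFactors = FALSE)
  dat <- utils::read.csv(path, header = FALSE, skip = 3, check.names = FALSE)
  parts <- as.character(unlist(hdr[2L, -1L]))
  coords <- as.character(unlist(hdr[3L, -1L]))
  bodypart <- bodypart %||% parts[1L]
  sel_x <- which(parts == bodypart & coords == "x")[1L] + 1L
  sel_y <- which(parts == bodypart & coords == "y")[1L] + 1L
  if (is.na(sel_x) || is.na(sel_y))
    ff_stop("ff_format_error", "body part '%s' not found", bodypart)
  out <- data.frame(time_s = (seq_len(nrow(dat)) - 1L) / rate_hz,
                    x = dat[[sel_x]], y = dat[[sel_y]])
  sel_l <- which(parts == bodypart & coords == "likelihood")
  if (length(sel_l)) out$likelihood <- dat[[sel_l[1L] + 1L]]
  out
}
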