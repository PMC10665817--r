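#' Real-time place preference score
#'
#' `(time during laser ON - time during laser OFF) / total time`, where ON
#' time is the summed occupancy of the laser-paired chamber and OFF time is
#' everything else (`session_len_s - ON`).
#'
#' @param occupancy Interval [event_series()] of laser-paired-chamber
#'   occupancy.
#' @param session_len_s Total session length (> 0).
#' @return Preference score in `[-1, 1]`.
#' @export
preference_score <- function(occupancy, session_len_s) {
  check_scalar(session_len_s, "session_len_s", lower = 0, strict_lower = TRUE)
  if (nrow(occupancy) > 0 &&
      (min(occupancy$start_s) < 0 || max(occupancy$end_s) > session_len_s))
    ff_stop("ff_data_error", "occupancy intervals outside the session")
  t_on <- sum(interval_durations(occupancy))
  t_off <- session_len_s - t_on
  (t_on - t_off) / session_len_s
}

#' Alternating laser-epoch schedule
#'
#' @param session_len_s Session length (s).
#' @param epoch_s Epoch length (s), default 120 (2-min alternation).
#' @param first_on Whether the first epoch has the laser on.
#' @return An `epoch_schedule` data frame `(start_s, end_s, laser_on)`
#'   tiling `[0, session_len_s]`.
#' @export
epoch_schedule <- function(session_len_s, epoch_s = 120, first_on = FALSE) {
  check_scalar(session_len_s, "session_len_s", lower = 0, strict_lower = TRUE)
  check_scalar(epoch_s, "epoch_s", lower = 0, strict_lower = TRUE)
  n_epochs <- ceiling(session_len_s / epoch_s - 1e-9)
  starts <- (seq_len(n_epochs) - 1L) * epoch_s
  ends <- pmin(starts + epoch_s, session_len_s)
  on <- rep(c(first_on, !first_on), length.out = length(starts))
  structure(data.frame(start_s = starts, end_s = ends, laser_on = on),
            session_len_s = session_len_s,
            class = c("epoch_schedule", "data.frame"))
}

#' Laser-epoch mobility and bout metrics
#'
#' Bouts are detected once on the whole session (same rules as
#' [detect_bouts()]); each mobility bout is attributed to the ON or OFF
#' condition by its onset time. Per condition: the mean mobility score over
#' the condition's epochs, the mean mobility within attributed bouts
#' (movement vigor), their mean duration, and their count.
#'
#' @param track A [behavior_track()].
#' @param schedule An [epoch_schedule()].
#' @param immobility_thresh,min_immobile_s Bout detection parameters.
#' @return Data frame with one row per condition (`laser_on` TRUE/FALSE):
#'   `mean_mobility`, `bout_vigor`, `mean_bout_dur_s`, `n_bouts`.
#' @export
epoch_metrics <- function(track, schedule, immobility_thresh = 0.1,
                          min_immobile_s = 2.0) {
  if (nrow(schedule) == 0L)
    ff_stop("ff_param_error", "empty epoch schedule")
  bouts <- detect_bouts(track, immobility_thresh, min_immobile_s)
  mob <- bouts[bouts$label == "mobility", , drop = FALSE]
  # condition of the epoch containing each bout onset
  epoch_of <- findInterval(mob$start_s, schedule$start_s)
  epoch_of[epoch_of < 1L] <- 1L
  bout_on <- schedule$laser_on[epoch_of]
  sample_epoch <- findInterval(track$time_s, schedule$start_s)
  sample_epoch[sample_epoch < 1L] <- 1L
  sample_on <- schedule$laser_on[sample_epoch]

  one_condition <- function(on) {
    sel <- bout_on == on
    in_bout <- rep(FALSE, nrow(track))
    for (i in which(sel))
      in_bout <- in_bout | (track$time_s >= mob$start_s[i] &
                              track$time_s < mob$end_s[i])
    data.frame(
      laser_on = on,
      mean_mobility = mean(track$mobility[sample_on == on]),
      bout_vigor = if (any(in_bout)) mean(track$mobility[in_bout]) else NA_real_,
      mean_bout_dur_s = if (any(sel))
        mean(mob$end_s[sel] - mob$start_s[sel]) else NA_real_,
      n_bouts = sum(sel)
    )
  }
  out <- rbind(one_condition(FALSE), one_condition(TRUE))
  rownames(out) <- NULL
  out
}

#' Consumption metrics for one session
#'
#' @param events Interval [event_series()] of consumption events (sorted,
#'   non-overlapping).
#' @param session_len_s Session length (s).
#' @return A `consumption_metrics` list: `mean_event_dur_s`,
#'   `mean_inter_event_interval_s` (gap between consecutive offset and next
#'   onset; `NA` + flag when fewer than 2 events), `n_events`, `total_dur_s`,
#'   `flags`.
#' @export
consumption_metrics <- function(events, session_len_s) {
  check_scalar(session_len_s, "session_len_s", lower = 0, strict_lower = TRUE)
  n <- nrow(events)
  flags <- character(0)
  if (n == 0L) {
    return(structure(list(mean_event_dur_s = 0,
                          mean_inter_event_interval_s = NA_real_,
                          n_events = 0L, total_dur_s = 0,
                          flags = c("no_events", "interval_undefined")),
                     class = "consumption_metrics"))
  }
  dur <- interval_durations(events)
  if (sum(dur) > session_len_s)
    ff_stop("ff_data_error", "total event duration exceeds the session length")
  interval <- if (n >= 2L) {
    mean(events$start_s[-1L] - events$end_s[-n])
  } else {
    flags <- c(flags, "interval_undefined")
    NA_real_
  }
  structure(list(mean_event_dur_s = mean(dur),
                 mean_inter_event_interval_s = interval,
                 n_events = n, total_dur_s = sum(dur), flags = flags),
            class = "consumption_metrics")
}

#' @export
print.consumption_metrics <- function(x, ...) {
  cat(sprintf("<consumption_metrics> n = %d, mean dur = %.3g s, mean interval = %.3g s, total = %.3g s\n",
              x$n_events, x$mean_event_dur_s, x$mean_inter_event_interval_s,
              x$total_dur_s))
  invisible(x)
}

#' Normalize stimulation-session metrics to baseline sessions
#'
#' Each metric of the photostimulation session is divided by the mean of the
#' same metric from the last pre-session and the post-session (both without
#' stimulation). A zero baseline yields `NA` flagged as undefined rather
#' than an error.
#'
#' @param stim,last_pre,post `consumption_metrics` objects.
#' @return List of normalized metrics (`mean_event_dur_s`,
#'   `mean_inter_event_interval_s`, `n_events`, `total_dur_s`) plus
#'   `undefined` naming metrics with zero baseline.
#' @export
normalize_to_baseline <- function(stim, last_pre, post) {
  metrics <- c("mean_event_dur_s", "mean_inter_event_interval_s",
               "n_events", "total_dur_s")
  out <- list()
  undefined <- character(0)
  for (m in metrics) {
    base <- mean(c(last_pre[[m]], post[[m]]))
    if (is.na(base) || base == 0) {
      out[[m]] <- NA_real_
      undefined <- c(undefined, m)
    } else {
      out[[m]] <- stim[[m]] / base
    }
  }
  out$undefined <- undefined
  out
}
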