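track_tv <- function(x) {
  if (inherits(x, "behavior_track")) list(t = x$time_s, v = x$mobility,
                                          rate = attr(x, "rate_hz"))
  else list(t = x$time_s, v = x$value, rate = attr(x, "rate_hz"))
}

#' Whole-session Pearson correlation between calcium and mobility
#'
#' Both series are linearly interpolated onto the grid of the lower nominal
#' rate over their overlapping support, then the Pearson coefficient and a
#' two-sided t-based p-value are computed.
#'
#' @param calcium A [photometry_trace()] (typically zdF/F).
#' @param mobility A [behavior_track()].
#' @return A `correlation_result` list: `r`, `p`, `n`, `degenerate`.
#' @export
session_pearson <- function(calcium, mobility) {
  a <- track_tv(calcium); b <- track_tv(mobility)
  lo <- max(a$t[1L], b$t[1L]); hi <- min(a$t[length(a$t)], b$t[length(b$t)])
  if (hi <= lo)
    ff_stop("ff_alignment_error", "no overlapping time support")
  rate <- min(a$rate, b$rate)
  grid <- seq(lo, hi, by = 1 / rate)
  if (length(grid) < 3L)
    ff_stop("ff_data_error", "fewer than 3 common samples")
  res <- pearson_rp(interp_at(a$t, a$v, grid), interp_at(b$t, b$v, grid))
  structure(res, class = "correlation_result")
}

#' @export
print.correlation_result <- function(x, ...) {
  if (isTRUE(x$degenerate))
    cat("<correlation_result> degenerate (zero-variance input)\n")
  else
    cat(sprintf("<correlation_result> r = %.4f, p = %.3g, n = %d\n",
                x$r, x$p, x$n))
  invisible(x)
}

# event-wise windowed Pearson between two series on a common grid
event_window_corr <- function(a, b, events, window_s, extra_s = 0) {
  lo_a <- a$t[1L]; hi_a <- a$t[length(a$t)]
  lo_b <- b$t[1L]; hi_b <- b$t[length(b$t)]
  half <- window_s / 2
  covered <- events - half - extra_s >= lo_a - 1e-9 &
    events + half + extra_s <= hi_a + 1e-9 &
    events - half >= lo_b - 1e-9 & events + half <= hi_b + 1e-9
  list(events = events[covered], n_excluded = sum(!covered))
}

#' Classify peri-event correlations
#'
#' For each event, the Pearson correlation between the calcium signal and
#' the mobility score over the event-centered `window_s` span (both resampled
#' to the lower of the two rates) is computed and classified: positive when
#' `p < p_thresh` and `r > r_pos`, negative when `p < p_thresh` and
#' `r < r_neg`, uncorrelated otherwise.
#'
#' @param calcium A [photometry_trace()].
#' @param mobility A [behavior_track()].
#' @param events Point [event_series()] or numeric times.
#' @param window_s Peri-event window length (s), centered on the event.
#' @param r_pos,r_neg Correlation thresholds for the positive/negative class.
#' @param p_thresh Two-sided p-value threshold.
#' @return An `event_class_counts` list: `n_positive`, `n_negative`,
#'   `n_uncorrelated`, `n_events`, `fractions`, `per_event` (data frame of
#'   r, p, class), `n_excluded`.
#' @export
classify_events <- function(calcium, mobility, events, window_s = 6.0,
                            r_pos = 0.6, r_neg = -0.6, p_thresh = 0.001) {
  if (inherits(events, "event_series")) events <- event_times(events)
  events <- sort(as.numeric(events))
  a <- track_tv(calcium); b <- track_tv(mobility)
  cov <- event_window_corr(a, b, events, window_s)
  if (cov$n_excluded > 0)
    ff_warn("ff_coverage_warning", "%d event(s) without full window coverage excluded",
            cov$n_excluded)
  events <- cov$events
  rate <- min(a$rate, b$rate)
  half <- window_s / 2
  rel <- seq(-half, half, by = 1 / rate)
  rs <- ps <- numeric(length(events))
  for (i in seq_along(events)) {
    xa <- interp_at(a$t, a$v, events[i] + rel)
    xb <- interp_at(b$t, b$v, events[i] + rel)
    res <- pearson_rp(xa, xb)
    rs[i] <- res$r; ps[i] <- res$p
  }
  cls <- rep("uncorrelated", length(events))
  cls[!is.na(rs) & ps < p_thresh & rs > r_pos] <- "positive"
  cls[!is.na(rs) & ps < p_thresh & rs < r_neg] <- "negative"
  n_pos <- sum(cls == "positive"); n_neg <- sum(cls == "negative")
  n_unc <- sum(cls == "uncorrelated")
  n <- length(events)
  structure(list(
    n_positive = n_pos, n_negative = n_neg, n_uncorrelated = n_unc,
    n_events = n,
    fractions = c(positive = n_pos, negative = n_neg,
                  uncorrelated = n_unc) / max(1L, n),
    per_event = data.frame(time_s = events, r = rs, p = ps, class = cls),
    n_excluded = cov$n_excluded
  ), class = "event_class_counts")
}

#' @export
print.event_class_counts <- function(x, ...) {
  cat(sprintf("<event_class_counts> %d events: %d positive, %d negative, %d uncorrelated (%d excluded)\n",
              x$n_events, x$n_positive, x$n_negative, x$n_uncorrelated,
              x$n_excluded))
  invisible(x)
}

#' Cross-correlation lag of maximum around events
#'
#' For each event and each signed lag `l` on the grid
#' `seq(-max_lag_s, max_lag_s, by = lag_step_s)`, the Pearson correlation
#' between the calcium trace evaluated at `t + l` and the mobility score at
#' `t` is computed over the event-centered window. The per-event lag of
#' maximum correlation is reported with ties broken toward the smallest
#' `|l|`. Sign convention: a negative `lag_at_max_s` means the calcium
#' signal leads mobility.
#'
#' @param calcium A [photometry_trace()].
#' @param mobility A [behavior_track()].
#' @param events Point [event_series()] or numeric times.
#' @param window_s Window length (s) centered on each event.
#' @param max_lag_s Maximum absolute lag (s).
#' @param lag_step_s Lag grid step; defaults to one sample of the common
#'   (lower-rate) grid.
#' @return A `lag_result` list: `lags_s`, `corr_vs_lag` (events x lags),
#'   `lag_at_max_s` (per event), `mean_curve`, `mean_lag_s`, `sem_lag_s`,
#'   `n_events`, `n_excluded`.
#' @export
crosscorr_lag <- function(calcium, mobility, events, window_s = 6.0,
                          max_lag_s = 2.0, lag_step_s = NULL) {
  if (inherits(events, "event_series")) events <- event_times(events)
  events <- sort(as.numeric(events))
  a <- track_tv(calcium); b <- track_tv(mobility)
  rate <- min(a$rate, b$rate)
  lag_step_s <- lag_step_s %||% (1 / rate)
  n_lag <- round(max_lag_s / lag_step_s)
  lags <- seq(-n_lag, n_lag) * lag_step_s
  cov <- event_window_corr(a, b, events, window_s, extra_s = max_lag_s)
  if (cov$n_excluded > 0)
    ff_warn("ff_coverage_warning",
            "%d event(s) without window + lag coverage excluded",
            cov$n_excluded)
  events <- cov$events
  if (!length(events))
    ff_stop("ff_empty_error", "no event has window + lag coverage")
  half <- window_s / 2
  rel <- seq(-half, half, by = 1 / rate)
  curves <- matrix(NA_real_, nrow = length(events), ncol = length(lags))
  lag_at_max <- numeric(length(events))
  for (i in seq_along(events)) {
    xb <- interp_at(b$t, b$v, events[i] + rel)
    for (j in seq_along(lags)) {
      xa <- interp_at(a$t, a$v, events[i] + rel + lags[j])
      curves[i, j] <- pearson_rp(xa, xb)$r
    }
    cv <- curves[i, ]
    best <- which(cv >= max(cv, na.rm = TRUE) - 1e-12)
    lag_at_max[i] <- lags[best[which.min(abs(lags[best]))]]
  }
  structure(list(
    lags_s = lags, corr_vs_lag = curves, lag_at_max_s = lag_at_max,
    mean_curve = colMeans(curves), mean_lag_s = mean(lag_at_max),
    sem_lag_s = if (length(lag_at_max) > 1)
      stats::sd(lag_at_max) / sqrt(length(lag_at_max)) else 0,
    n_events = length(events), n_excluded = cov$n_excluded
  ), class = "lag_result")
}

#' @export
print.lag_result <- function(x, ...) {
  cat(sprintf("<lag_result> %d events, mean lag at max = %.3f +/- %.3f s (%d excluded)\n",
              x$n_events, x$mean_lag_s, x$sem_lag_s, x$n_excluded))
  invisible(x)
}
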