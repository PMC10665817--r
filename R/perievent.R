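#' Extract peri-event trials onto a common relative-time grid
#'
#' Each event with full coverage (`[event - pre_s, event + post_s]` inside
#' the trace support) contributes one row, linearly interpolated onto the
#' uniform grid `seq(-pre_s, post_s, by = 1/grid_rate_hz)`. Events without
#' full coverage are dropped and counted, never padded.
#'
#' @param trace A [photometry_trace()] or [behavior_track()] (its `mobility`
#'   column is used).
#' @param events Point [event_series()] or numeric event times (s).
#' @param pre_s,post_s Window extent before/after the event (s).
#' @param grid_rate_hz Grid rate; defaults to the trace's nominal rate.
#' @return A `perievent_matrix`: list with `rel_time_s`, `values`
#'   (trials x grid), `event_times_s`, `n_dropped`, `source_label`.
#' @export
extract_perievent <- function(trace, events, pre_s = 5, post_s = 5,
                              grid_rate_hz = NULL) {
  if (inherits(events, "event_series")) {
    if (attr(events, "type") != "point")
      ff_stop("ff_param_error", "events must be point events")
    events <- events$time_s
  }
  events <- sort(as.numeric(events))
  if (inherits(trace, "behavior_track")) {
    tv <- trace$time_s; vv <- trace$mobility
    label <- "mobility"
  } else {
    tv <- trace$time_s; vv <- trace$value
    label <- paste0(attr(trace, "channel") %||% "trace", "/",
                    attr(trace, "roi") %||% "")
  }
  rate <- grid_rate_hz %||% attr(trace, "rate_hz") %||%
    (1 / stats::median(diff(tv)))
  rel <- seq(-pre_s, post_s, by = 1 / rate)
  lo <- tv[1L]; hi <- tv[length(tv)]
  keep <- events - pre_s >= lo - 1e-9 & events + post_s <= hi + 1e-9
  n_dropped <- sum(!keep)
  events <- events[keep]
  if (!length(events))
    ff_stop("ff_empty_error", "no event has full peri-event coverage")
  values <- t(vapply(events, function(e) interp_at(tv, vv, e + rel),
                     numeric(length(rel))))
  structure(list(rel_time_s = rel, values = values, event_times_s = events,
                 n_dropped = n_dropped, source_label = label),
            class = "perievent_matrix")
}

#' @export
print.perievent_matrix <- function(x, ...) {
  cat(sprintf("<perievent_matrix> %d trial(s) x %d samples, rel time %.2f..%.2f s (%d dropped)\n",
              nrow(x$values), length(x$rel_time_s), min(x$rel_time_s),
              max(x$rel_time_s), x$n_dropped))
  invisible(x)
}

#' Trial mean and SEM of a peri-event matrix
#'
#' @param pem A `perievent_matrix`.
#' @return List with `rel_time_s`, `mean`, `sem` (`sd/sqrt(n)`; zeros with
#'   attribute `single_trial = TRUE` when `n = 1`), and `n`.
#' @export
trial_mean <- function(pem) {
  v <- pem$values
  n <- nrow(v)
  if (n < 1L) ff_stop("ff_empty_error", "no trials")
  m <- colMeans(v)
  if (n == 1L) {
    sem <- rep(0, ncol(v))
    attr(sem, "single_trial") <- TRUE
  } else {
    sem <- apply(v, 2L, stats::sd) / sqrt(n)
  }
  list(rel_time_s = pem$rel_time_s, mean = m, sem = sem, n = n)
}

#' Named AUC windows per behavioral test
#'
#' The analysis windows (seconds relative to the event) used by the
#' windowed-AUC statistics for each test.
#'
#' @param test_name One of `"airpuff"`, `"consumption"`, `"mobility"`,
#'   `"avoidance"`.
#' @return A `window_spec`: named list of `c(t0, t1)` windows.
#' @export
window_table <- function(test_name) {
  tables <- list(
    airpuff = list(baseline = c(-2, -1), airpuff = c(0, 1.5)),
    consumption = list(baseline = c(-2, -1), onset = c(-0.5, 1),
                       drinking = c(2, 4)),
    mobility = list(immobile = c(-3, -1), pre_onset = c(-1, 0),
                    onset = c(0, 1), mobility = c(1, 3)),
    avoidance = list(baseline = c(-2, -1), CS = c(0, 8), crossed = c(8, 11))
  )
  if (!test_name %in% names(tables))
    ff_stop("ff_key_error", "unknown test '%s'; known: %s", test_name,
            paste(names(tables), collapse = ", "))
  structure(tables[[test_name]], test_name = test_name,
            class = c("window_spec", "list"))
}

# trapezoidal integral of (t, y) over [t0, t1], with the window endpoints
# interpolated onto the curve so off-grid bounds are exact for piecewise
# linear inputs
trapz_window <- function(t, y, t0, t1) {
  if (t0 < t[1L] - 1e-9 || t1 > t[length(t)] + 1e-9)
    ff_stop("ff_range_error",
            "window [%g, %g] outside the grid [%g, %g]", t0, t1,
            t[1L], t[length(t)])
  inner <- t > t0 & t < t1
  tt <- c(t0, t[inner], t1)
  yy <- c(stats::approx(t, y, xout = t0, rule = 2)$y, y[inner],
          stats::approx(t, y, xout = t1, rule = 2)$y)
  sum(diff(tt) * (yy[-1L] + yy[-length(yy)]) / 2)
}

#' Normalized AUC over a named window
#'
#' Trapezoidal area under each trial's curve over `[t0, t1]`, normalized by
#' the window duration: `AUCnorm = AUC / (t1 - t0)`. A constant trace of
#' value `c` therefore has normalized AUC `c` over any window.
#'
#' @param x A `perievent_matrix`, or a list with `rel_time_s` and a curve in
#'   `mean` (e.g. the output of [trial_mean()]).
#' @param window Length-2 numeric `c(t0, t1)` with `t1 > t0`, inside the
#'   grid.
#' @return List with `per_trial` (normalized AUC per trial) and `mean`.
#' @export
perievent_auc <- function(x, window) {
  if (length(window) != 2L || window[2L] <= window[1L])
    ff_stop("ff_param_error", "window must be c(t0, t1) with t1 > t0")
  if (inherits(x, "perievent_matrix")) {
    t <- x$rel_time_s
    vals <- apply(x$values, 1L, trapz_window, t = t,
                  t0 = window[1L], t1 = window[2L])
  } else {
    t <- x$rel_time_s
    vals <- trapz_window(t, x$mean, window[1L], window[2L])
  }
  vals <- vals / diff(window)
  list(per_trial = vals, mean = mean(vals))
}

#' Windowed AUC table for one test
#'
#' Applies every window of [window_table()] for `test_name` to a peri-event
#' matrix.
#'
#' @param pem A `perievent_matrix`.
#' @param test_name Test tag understood by [window_table()].
#' @return Data frame with one row per (trial, window): `trial`, `window`,
#'   `auc_norm`.
#' @export
auc_table <- function(pem, test_name) {
  spec <- window_table(test_name)
  out <- do.call(rbind, lapply(names(spec), function(w) {
    a <- perievent_auc(pem, spec[[w]])
    data.frame(trial = seq_along(a$per_trial), window = w,
               auc_norm = a$per_trial)
  }))
  rownames(out) <- NULL
  out
}
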