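#' Preprocessing parameters for the zdF/F chain
#'
#' @param smooth_window_s Width (s) of the centered moving average. Exactly
#'   one of `smooth_window_s` / `lowpass_cutoff_hz` must be set.
#' @param lowpass_cutoff_hz Cutoff (Hz) of a zero-phase 2nd-order Butterworth
#'   low-pass (forward-backward filtered), as an alternative smoother.
#' @param airpls_lambda Smoothness penalty of the airPLS baseline (> 0).
#'   The baseline's effective timescale is roughly `lambda^(1/4)` samples;
#'   the default 1e9 (about 18 s at 10 Hz) tracks minutes-scale
#'   photobleaching while leaving multi-second calcium elevations intact.
#' @param airpls_max_iter Maximum reweighting iterations (>= 1).
#' @param airpls_tol Convergence threshold as a fraction of the total
#'   absolute signal.
#' @param l1_alpha L1 regularization weight of the reference fit (>= 0).
#' @param sd_floor Minimum standard deviation below which a trace is flagged
#'   degenerate by [standardize()].
#' @return A validated `preprocess_params` list.
#' @export
preprocess_params <- function(smooth_window_s = 1, lowpass_cutoff_hz = NULL,
                              airpls_lambda = 1e9, airpls_max_iter = 50L,
                              airpls_tol = 1e-3, l1_alpha = 1e-4,
                              sd_floor = 1e-8) {
  if (!is.null(smooth_window_s) && !is.null(lowpass_cutoff_hz))
    ff_stop("ff_param_error",
            "set exactly one of smooth_window_s / lowpass_cutoff_hz")
  if (is.null(smooth_window_s) && is.null(lowpass_cutoff_hz))
    ff_stop("ff_param_error",
            "set exactly one of smooth_window_s / lowpass_cutoff_hz")
  if (!is.null(smooth_window_s))
    check_scalar(smooth_window_s, "smooth_window_s", lower = 0, strict_lower = TRUE)
  if (!is.null(lowpass_cutoff_hz))
    check_scalar(lowpass_cutoff_hz, "lowpass_cutoff_hz", lower = 0,
                 strict_lower = TRUE)
  check_scalar(airpls_lambda, "airpls_lambda", lower = 0, strict_lower = TRUE)
  check_scalar(airpls_max_iter, "airpls_max_iter", lower = 1)
  check_scalar(airpls_tol, "airpls_tol", lower = 0, strict_lower = TRUE)
  check_scalar(l1_alpha, "l1_alpha", lower = 0)
  check_scalar(sd_floor, "sd_floor", lower = 0, strict_lower = TRUE)
  structure(list(smooth_window_s = smooth_window_s,
                 lowpass_cutoff_hz = lowpass_cutoff_hz,
                 airpls_lambda = airpls_lambda,
                 airpls_max_iter = as.integer(airpls_max_iter),
                 airpls_tol = airpls_tol, l1_alpha = l1_alpha,
                 sd_floor = sd_floor),
            class = "preprocess_params")
}

# centered moving average with shrinking windows at the edges (same length,
# zero phase, DC preserved)
moving_average <- function(y, k) {
  n <- length(y)
  half <- (k - 1L) %/% 2L
  cs <- cumsum(c(0, y))
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

#' Smooth a photometry trace
#'
#' Default is a centered moving average of `smooth_window_s` seconds (kernel
#' length rounded to the nearest odd sample count; edges use shrinking
#' windows). With `lowpass_cutoff_hz` set instead, a zero-phase Butterworth
#' low-pass is applied via forward-backward filtering. Both preserve length,
#' timestamps, and phase.
#'
#' @param trace A [photometry_trace()].
#' @param params A [preprocess_params()].
#' @return The smoothed trace.
#' @export
smooth_trace <- function(trace, params = preprocess_params()) {
  rate <- trace_rate(trace)
  y <- trace$value
  if (!is.null(params$smooth_window_s)) {
    k <- max(1L, round(params$smooth_window_s * rate))
    if (k %% 2L == 0L) k <- k + 1L
    if (k > length(y))
      ff_stop("ff_data_error",
              "trace (%d samples) shorter than smoothing kernel (%d)",
              length(y), k)
    ys <- moving_average(y, k)
  } else {
    if (params$lowpass_cutoff_hz >= rate / 2)
      ff_stop("ff_param_error",
              "lowpass_cutoff_hz must be below the Nyquist rate %.3g Hz",
              rate / 2)
    bf <- signal::butter(2, params$lowpass_cutoff_hz / (rate / 2), type = "low")
    if (length(y) <= 3 * max(length(bf$a), length(bf$b)))
      ff_stop("ff_data_error", "trace too short for zero-phase filtering")
    ys <- as.numeric(signal::filtfilt(bf, y))
  }
  photometry_trace(trace$time_s, ys, channel = attr(trace, "channel"),
                   roi = attr(trace, "roi"), rate_hz = rate,
                   units = attr(trace, "units"))
}

# weighted Whittaker smoother: solves (W + lambda D'D) z = W y with
# second-order differences, via a sparse Cholesky factorization
whittaker_weighted <- function(y, w, lambda) {
  n <- length(y)
  D <- Matrix::bandSparse(n - 2L, n,
                          k = 0:2,
                          diagonals = list(rep(1, n - 2L), rep(-2, n - 2L),
                                           rep(1, n - 2L)))
  A <- Matrix::Diagonal(n, x = w) + lambda * Matrix::crossprod(D)
  as.numeric(Matrix::solve(A, w * y))
}

#' airPLS baseline estimation
#'
#' Adaptive iteratively reweighted penalized least squares: each iteration
#' solves a weighted Whittaker smoothing problem with a second-order
#' difference penalty weighted by `lambda`, then reassigns weights so points
#' above the running baseline (peaks) get zero weight and points below get
#' exponentially increasing weight in their residual magnitude:
#' `w_i = exp(iter * |d_i| / |D|)` for negative residuals `d_i`, with
#' `|D|` the summed magnitude of negative residuals; the first and last
#' weights are anchored at `exp(iter * max|d_neg| / |D|)`. Iteration stops
#' when `|D| < tol * sum(|y|)` or at `max_iter`.
#'
#' @param y Numeric vector (length >= 3, finite).
#' @param lambda Smoothness penalty (> 0).
#' @param max_iter Maximum iterations.
#' @param tol Convergence fraction of total absolute signal.
#' @return The baseline (same length as `y`) with attributes `iterations`
#'   (iterations used) and `criterion_path` (the negative-residual sum after
#'   each solve).
#' @export
airpls_baseline <- function(y, lambda = 1e9, max_iter = 50L, tol = 1e-3) {
  if (length(y) < 3L)
    ff_stop("ff_data_error", "airPLS needs at least 3 samples")
  if (any(!is.finite(y)))
    ff_stop("ff_data_error", "airPLS input contains non-finite values")
  check_scalar(lambda, "lambda", lower = 0, strict_lower = TRUE)
  n <- length(y)
  w <- rep(1, n)
  total <- sum(abs(y))
  z <- y
  path <- numeric(0)
  iters <- 0L
  for (i in seq_len(max_iter)) {
    z <- whittaker_weighted(y, w, lambda)
    d <- y - z
    neg <- d < 0
    dssn <- sum(abs(d[neg]))
    path <- c(path, dssn)
    iters <- i
    if (dssn < tol * total) break
    w[!neg] <- 0
    w[neg] <- exp(i * abs(d[neg]) / dssn)
    anchor <- if (any(neg)) exp(i * max(abs(d[neg])) / dssn) else 1
    w[1L] <- anchor
    w[n] <- anchor
  }
  structure(z, iterations = iters, criterion_path = path)
}

#' Standardize to zero mean and unit standard deviation
#'
#' @param y Numeric vector (length >= 2).
#' @param sd_floor Minimum sd; below it the input is treated as constant and
#'   a vector of zeros is returned with attribute `degenerate = TRUE`.
#' @return The z-scored vector, with attributes `center`, `scale`, and
#'   `degenerate`.
#' @export
standardize <- function(y, sd_floor = 1e-8) {
  if (length(y) < 2L)
    ff_stop("ff_data_error", "standardize needs at least 2 samples")
  m <- mean(y)
  s <- stats::sd(y)
  if (!is.finite(s) || s < sd_floor)
    return(structure(rep(0, length(y)), center = m, scale = NA_real_,
                     degenerate = TRUE))
  structure((y - m) / s, center = m, scale = s, degenerate = FALSE)
}

#' Fit the reference channel to the signal channel
#'
#' Non-negative L1-regularized least squares with a single predictor:
#' minimizes `(1/2n) * sum((signal - a*reference - b)^2) + alpha * |a|`
#' subject to `a >= 0`. With one predictor the solution is closed-form: the
#' slope is the soft-thresholded, non-negativity-clipped least-squares
#' coefficient and the intercept re-centers the fit.
#'
#' @param reference_std Standardized reference values.
#' @param signal_std Standardized signal values (same length).
#' @param l1_alpha Regularization weight (>= 0).
#' @return A `fit_result` list: `slope_a`, `intercept_b`, `fitted_reference`.
#' @export
fit_reference <- function(reference_std, signal_std, l1_alpha = 1e-4) {
  if (length(reference_std) != length(signal_std))
    ff_stop("ff_data_error", "reference and signal lengths differ (%d vs %d)",
            length(reference_std), length(signal_std))
  if (length(signal_std) < 2L)
    ff_stop("ff_data_error", "fit needs at least 2 samples")
  check_scalar(l1_alpha, "l1_alpha", lower = 0)
  n <- length(signal_std)
  rbar <- mean(reference_std); sbar <- mean(signal_std)
  rc <- reference_std - rbar; sc <- signal_std - sbar
  ss_r <- sum(rc^2) / n
  if (ss_r == 0) {
    a <- 0
  } else {
    cov_rs <- sum(rc * sc) / n
    a <- max(0, (cov_rs - l1_alpha) / ss_r)
  }
  b <- sbar - a * rbar
  structure(list(slope_a = a, intercept_b = b,
                 fitted_reference = a * reference_std + b),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat(sprintf("<fit_result> slope_a = %.6g, intercept_b = %.6g\n",
              x$slope_a, x$intercept_b))
  invisible(x)
}

#' Compute zdF/F from a signal and a reference trace
#'
#' The full correction chain: both traces are smoothed, flattened by
#' subtracting an airPLS baseline, and standardized; the standardized
#' reference is linearly interpolated onto the signal's timestamps and
#' fitted to the standardized signal by non-negative L1-regularized least
#' squares; zdF/F is the standardized signal minus the fitted reference.
#'
#' @param signal Calcium-dependent [photometry_trace()].
#' @param reference Calcium-independent [photometry_trace()] (isosbestic
#'   channel) with overlapping time support.
#' @param params A [preprocess_params()].
#' @return A [photometry_trace()] in zdF/F units on the signal's timestamps,
#'   with attributes `fit` (the [fit_reference()] result), `airpls_iterations`
#'   (signal/reference iterations used), and `degenerate` flags.
#' @export
compute_zdff <- function(signal, reference, params = preprocess_params()) {
  t_lo <- max(signal$time_s[1L], reference$time_s[1L])
  t_hi <- min(signal$time_s[nrow(signal)], reference$time_s[nrow(reference)])
  if (t_hi <= t_lo)
    ff_stop("ff_alignment_error",
            "signal and reference have no overlapping time support")

  sm_sig <- smooth_trace(signal, params)
  sm_ref <- smooth_trace(reference, params)

  base_sig <- airpls_baseline(sm_sig$value, params$airpls_lambda,
                              params$airpls_max_iter, params$airpls_tol)
  base_ref <- airpls_baseline(sm_ref$value, params$airpls_lambda,
                              params$airpls_max_iter, params$airpls_tol)

  z_sig <- standardize(sm_sig$value - as.numeric(base_sig), params$sd_floor)
  z_ref <- standardize(sm_ref$value - as.numeric(base_ref), params$sd_floor)

  # clip the signal grid to the overlap so the reference never extrapolates
  keep <- signal$time_s >= t_lo - 1e-9 & signal$time_s <= t_hi + 1e-9
  t_out <- signal$time_s[keep]
  z_sig_out <- as.numeric(z_sig)[keep]
  z_ref_interp <- interp_at(reference$time_s, as.numeric(z_ref), t_out)

  fit <- fit_reference(z_ref_interp, z_sig_out, params$l1_alpha)
  zdff <- z_sig_out - fit$fitted_reference

  out <- photometry_trace(t_out, zdff, channel = attr(signal, "channel"),
                          roi = attr(signal, "roi"),
                          rate_hz = trace_rate(signal), units = "zdff")
  attr(out, "fit") <- fit
  attr(out, "airpls_iterations") <- c(signal = attr(base_sig, "iterations"),
                                      reference = attr(base_ref, "iterations"))
  attr(out, "degenerate") <- c(signal = attr(z_sig, "degenerate"),
                               reference = attr(z_ref, "degenerate"))
  out
}
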