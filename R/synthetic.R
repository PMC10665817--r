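#' Synthetic-session configuration
#'
#' Parameters of the generative model behind [generate_session()]. The
#' acquisition geometry mirrors a frame-multiplexed multi-LED photometry rig:
#' a camera at `camera_rate_hz` cycles through the excitation LEDs so each
#' channel is sampled at `camera_rate_hz / length(led_channels)`. All other
#' parameters describe the latent structure (photobleaching drift, shared
#' motion artifacts, calcium transients, mobility bouts, licks) that the
#' downstream analysis is expected to recover.
#'
#' @param duration_s Session length in seconds (> 0).
#' @param camera_rate_hz Camera frame rate (default 20 Hz; two alternating
#'   LEDs then give 10 Hz per channel).
#' @param led_channels Ordered excitation labels; LED-state codes are the
#'   bitmask 1, 2, 4 for the first, second, third channel.
#' @param signal_channel Which label carries calcium-dependent fluorescence;
#'   the remaining channels are calcium-independent references.
#' @param baseline_level Mean fluorescence level in camera units.
#' @param bleach_amp,bleach_tau_s Double-exponential photobleaching drift:
#'   amplitude (camera units) and fast time constant (s); the slow component
#'   has time constant `5 * bleach_tau_s` and 40% of the amplitude.
#' @param artifact_rate_hz Poisson rate of shared motion artifacts (default
#'   0.5 Hz: a freely moving animal bends the patch cord every couple of
#'   seconds).
#' @param artifact_amp Artifact peak amplitude (camera units); artifacts are
#'   random-sign biexponential bumps added to every channel with a
#'   channel-specific gain.
#' @param artifact_ref_gain Artifact gain on the reference (non-signal)
#'   channels relative to the signal channel's gain of 1; 1 means perfect
#'   artifact sharing across wavelengths.
#' @param transient_rate_hz Poisson rate of background calcium transients.
#' @param transient_amp Transient peak amplitude (camera units).
#' @param kernel_rise_s,kernel_decay_s Difference-of-exponentials transient
#'   kernel time constants (`kernel_decay_s > kernel_rise_s > 0`), normalized
#'   to unit peak.
#' @param noise_sd Per-frame additive Gaussian noise (camera units).
#' @param coupling_lag_s Signed lead of the calcium bout-coupled component
#'   relative to mobility (negative = calcium first).
#' @param coupling_amp Amplitude of the bout-coupled calcium component
#'   (camera units); 0 decouples calcium from behavior.
#' @param bout_mean_dur_s,immobility_mean_dur_s Mean durations of mobility /
#'   immobility bouts (shifted-exponential: minimum 2 s mobile, 3 s immobile).
#' @param lick_params List with `bout_rate_hz` (lick-bout Poisson rate),
#'   `lick_rate_hz` (within-bout lick rate), `licks_per_bout_mean`, and
#'   `contact_dur_s` (single contact duration).
#' @param seed Integer seed; identical configs give bit-identical sessions.
#' @return A validated `synth_config` list.
#' @export
synth_config <- function(duration_s = 600, camera_rate_hz = 20,
                         led_channels = c("415", "470"),
                         signal_channel = "470",
                         baseline_level = 100,
                         bleach_amp = 20, bleach_tau_s = 120,
                         artifact_rate_hz = 0.5, artifact_amp = 10,
                         artifact_ref_gain = 0.5,
                         transient_rate_hz = 0.1, transient_amp = 5,
                         kernel_rise_s = 0.2, kernel_decay_s = 1.0,
                         noise_sd = 2.5,
                         coupling_lag_s = 0, coupling_amp = 5,
                         bout_mean_dur_s = 8, immobility_mean_dur_s = 10,
                         lick_params = list(bout_rate_hz = 0.02,
                                            lick_rate_hz = 7,
                                            licks_per_bout_mean = 20,
                                            contact_dur_s = 0.08),
                         seed = 1L) {
  check_scalar(duration_s, "duration_s", lower = 0, strict_lower = TRUE)
  check_scalar(camera_rate_hz, "camera_rate_hz", lower = 0, strict_lower = TRUE)
  if (length(led_channels) < 1L || length(led_channels) > 3L)
    ff_stop("ff_param_error", "'led_channels' must list 1 to 3 channels")
  if (anyDuplicated(led_channels))
    ff_stop("ff_param_error", "'led_channels' must be distinct")
  if (!signal_channel %in% led_channels)
    ff_stop("ff_param_error", "'signal_channel' must be one of led_channels")
  check_scalar(bleach_amp, "bleach_amp", lower = 0)
  check_scalar(bleach_tau_s, "bleach_tau_s", lower = 0, strict_lower = TRUE)
  check_scalar(artifact_rate_hz, "artifact_rate_hz", lower = 0)
  check_scalar(artifact_amp, "artifact_amp", lower = 0)
  check_scalar(artifact_ref_gain, "artifact_ref_gain", lower = 0)
  check_scalar(transient_rate_hz, "transient_rate_hz", lower = 0)
  check_scalar(transient_amp, "transient_amp", lower = 0)
  check_scalar(kernel_rise_s, "kernel_rise_s", lower = 0, strict_lower = TRUE)
  if (kernel_decay_s <= kernel_rise_s)
    ff_stop("ff_param_error", "'kernel_decay_s' must exceed kernel_rise_s")
  check_scalar(noise_sd, "noise_sd", lower = 0)
  check_scalar(coupling_lag_s, "coupling_lag_s")
  check_scalar(coupling_amp, "coupling_amp", lower = 0)
  check_scalar(bout_mean_dur_s, "bout_mean_dur_s", lower = 2, strict_lower = TRUE)
  check_scalar(immobility_mean_dur_s, "immobility_mean_dur_s", lower = 3,
               strict_lower = TRUE)
  for (f in c("bout_rate_hz", "lick_rate_hz", "licks_per_bout_mean",
              "contact_dur_s"))
    check_scalar(lick_params[[f]], paste0("lick_params$", f), lower = 0)
  if (!is.numeric(seed) || length(seed) != 1L)
    ff_stop("ff_param_error", "'seed' must be a single integer")
  structure(list(
    duration_s = duration_s, camera_rate_hz = camera_rate_hz,
    led_channels = as.character(led_channels),
    signal_channel = as.character(signal_channel),
    baseline_level = baseline_level,
    bleach_amp = bleach_amp, bleach_tau_s = bleach_tau_s,
    artifact_rate_hz = artifact_rate_hz, artifact_amp = artifact_amp,
    artifact_ref_gain = artifact_ref_gain,
    transient_rate_hz = transient_rate_hz, transient_amp = transient_amp,
    kernel_rise_s = kernel_rise_s, kernel_decay_s = kernel_decay_s,
    noise_sd = noise_sd,
    coupling_lag_s = coupling_lag_s, coupling_amp = coupling_amp,
    bout_mean_dur_s = bout_mean_dur_s,
    immobility_mean_dur_s = immobility_mean_dur_s,
    lick_params = lick_params, seed = as.integer(seed)
  ), class = "synth_config")
}

# unit-peak difference-of-exponentials kernel evaluated at times t >= 0
transient_kernel <- function(t, rise_s, decay_s) {
  k <- ifelse(t < 0, 0, exp(-t / decay_s) - exp(-t / rise_s))
  tp <- rise_s * decay_s / (decay_s - rise_s) * log(decay_s / rise_s)
  peak <- exp(-tp / decay_s) - exp(-tp / rise_s)
  k / peak
}

# sum of unit-peak kernels at `times`, amplitude `amp`, on grid `t`
render_bumps <- function(t, times, amp, rise_s, decay_s) {
  out <- numeric(length(t))
  for (tt in times) {
    i0 <- findInterval(tt, t)
    idx <- seq.int(max(1L, i0), length(t))
    # kernels are negligible past ~10 decay constants
    idx <- idx[t[idx] - tt <= 10 * decay_s]
    if (length(idx))
      out[idx] <- out[idx] + amp * transient_kernel(t[idx] - tt, rise_s, decay_s)
  }
  out
}

# alternating immobility/mobility bout plan covering [0, duration]
plan_bouts <- function(duration_s, mob_mean, imm_mean) {
  mob_min <- 2; imm_min <- 3
  starts <- numeric(0); ends <- numeric(0); labels <- character(0)
  t <- 0; immobile <- TRUE
  while (t < duration_s) {
    dur <- if (immobile) imm_min + stats::rexp(1, 1 / (imm_mean - imm_min))
           else mob_min + stats::rexp(1, 1 / (mob_mean - mob_min))
    e <- min(t + dur, duration_s)
    starts <- c(starts, t); ends <- c(ends, e)
    labels <- c(labels, if (immobile) "immobility" else "mobility")
    t <- e; immobile <- !immobile
  }
  data.frame(start_s = starts, end_s = ends, label = labels)
}

# piecewise waveform: 0 in immobility, 1 in mobility, 0.3-s linear ramps
# starting at each transition
bout_waveform <- function(t, bouts, ramp_s = 0.3) {
  v <- numeric(length(t))
  for (i in seq_len(nrow(bouts))) {
    if (bouts$label[i] != "mobility") next
    s <- bouts$start_s[i]; e <- bouts$end_s[i]
    up <- t >= s & t < s + ramp_s
    v[up] <- pmax(v[up], (t[up] - s) / ramp_s)
    flat <- t >= s + ramp_s & t < e
    v[flat] <- 1
    down <- t >= e & t < e + ramp_s
    v[down] <- pmax(v[down], 1 - (t[down] - e) / ramp_s)
  }
  v
}

#' Generate a complete synthetic session
#'
#' Simulates a frame-multiplexed photometry recording together with a
#' behavior track and event logs, returning the latent variables
#' (`ground_truth`) that downstream stages should recover. The
#' calcium-dependent channel is drift + shared artifact + bout-coupled
#' calcium + background transients + noise; reference channels carry their
#' own drift and the same artifact (scaled) but no calcium. The bout-coupled
#' calcium component is the clean mobility waveform shifted by
#' `coupling_lag_s` (negative = calcium leads), so cross-correlation against
#' the mobility score has a well-defined maximum at the true lag.
#'
#' @param config A [synth_config()].
#' @return A list with elements `recording` (an `interleaved_recording`),
#'   `behavior` (a [behavior_track()]), `events` (named list of
#'   [event_series()]: `lick`, `mobility_onset`), and `ground_truth` (list of
#'   latents: `transient_times`, `clean_transient_trace`, `drift_traces`,
#'   `artifact_trace`, `artifact_gains`, `mobility_onsets`, `true_lag_s`,
#'   `lick_intervals`, `bouts`).
#' @export
generate_session <- function(config) {
  if (!inherits(config, "synth_config"))
    ff_stop("ff_param_error", "'config' must be a synth_config")
  with_local_seed(config$seed, {
    n_ch <- length(config$led_channels)
    codes <- c(1L, 2L, 4L)[seq_len(n_ch)]
    n_frames <- floor(config$duration_s * config$camera_rate_hz)
    t_frame <- (seq_len(n_frames) - 1L) / config$camera_rate_hz
    led_state <- rep_len(codes, n_frames)
    ch_of_frame <- rep_len(seq_len(n_ch), n_frames)

    # behavior: alternating bouts, ramped waveform, raw speed, mobility score
    bouts <- plan_bouts(config$duration_s, config$bout_mean_dur_s,
                        config$immobility_mean_dur_s)
    wave <- bout_waveform(t_frame, bouts)
    speed_scale <- 12  # cm/s at full mobility, arbitrary tracking units
    raw_speed <- pmax(0, speed_scale * (0.03 + 0.92 * wave) +
                        stats::rnorm(n_frames, 0, 0.05))
    behavior <- mobility_score(raw_speed, time_s = t_frame)

    mob_onsets <- bouts$start_s[bouts$label == "mobility"]

    # calcium latents on the full camera grid
    coupled_times <- sort(mob_onsets + config$coupling_lag_s)
    coupled_times <- coupled_times[coupled_times >= 0 &
                                     coupled_times <= config$duration_s]
    shifted_wave <- bout_waveform(t_frame - config$coupling_lag_s, bouts)
    n_bg <- stats::rpois(1, config$transient_rate_hz * config$duration_s)
    bg_times <- sort(stats::runif(n_bg, 0, config$duration_s))
    clean <- config$coupling_amp * shifted_wave +
      render_bumps(t_frame, bg_times, config$transient_amp,
                   config$kernel_rise_s, config$kernel_decay_s)
    transient_times <- sort(c(coupled_times, bg_times))

    # shared motion artifact (random sign, fast biexponential bumps)
    n_art <- stats::rpois(1, config$artifact_rate_hz * config$duration_s)
    art_times <- sort(stats::runif(n_art, 0, config$duration_s))
    art_signs <- if (n_art > 0) sample(c(-1, 1), n_art, replace = TRUE) else numeric(0)
    artifact <- numeric(n_frames)
    for (i in seq_len(n_art))
      artifact <- artifact +
        render_bumps(t_frame, art_times[i], art_signs[i] * config$artifact_amp,
                     0.05, 0.5)

    # per-channel drift (each channel has its own level/bleach scaling)
    drift_traces <- vector("list", n_ch)
    names(drift_traces) <- config$led_channels
    gains <- ifelse(config$led_channels == config$signal_channel, 1.0,
                    config$artifact_ref_gain)
    values <- numeric(n_frames)
    noise <- stats::rnorm(n_frames, 0, config$noise_sd)
    for (k in seq_len(n_ch)) {
      lvl <- config$baseline_level * (1 - 0.1 * (k - 1))
      drift <- lvl + config$bleach_amp * (1 - 0.1 * (k - 1)) *
        (0.6 * exp(-t_frame / config$bleach_tau_s) +
           0.4 * exp(-t_frame / (5 * config$bleach_tau_s)))
      drift_traces[[k]] <- drift
      sel <- ch_of_frame == k
      is_sig <- config$led_channels[k] == config$signal_channel
      values[sel] <- drift[sel] + gains[k] * artifact[sel] +
        (if (is_sig) clean[sel] else 0) + noise[sel]
    }

    rec <- interleaved_recording(
      frame_index = seq_len(n_frames) - 1L,
      timestamp_s = t_frame, led_state = led_state,
      values = data.frame(Region0 = values),
      channel_map = stats::setNames(config$led_channels, codes)
    )

    licks <- generate_lick_train(config)

    sig_sel <- config$led_channels[ch_of_frame] == config$signal_channel
    gt <- list(
      transient_times = transient_times,
      clean_transient_trace = photometry_trace(
        t_frame[sig_sel], clean[sig_sel],
        channel = config$signal_channel, roi = "Region0",
        rate_hz = config$camera_rate_hz / n_ch),
      clean_full_grid = clean,
      drift_traces = drift_traces,
      artifact_trace = artifact,
      artifact_gains = stats::setNames(gains, config$led_channels),
      frame_channel = config$led_channels[ch_of_frame],
      mobility_onsets = mob_onsets,
      true_lag_s = config$coupling_lag_s,
      lick_intervals = licks,
      lick_bouts = attr(licks, "bouts"),
      bouts = bouts
    )

    list(recording = rec, behavior = behavior,
         events = list(
           lick = licks,
           mobility_onset = event_series(times_s = mob_onsets,
                                         label = "mobility_onset")),
         ground_truth = gt)
  })
}

#' Generate a lick-contact train with bout structure
#'
#' Lick bouts start at Poisson times (thinned so that consecutive bouts are
#' separated by more than 1 s); within a bout, contacts occur at
#' `lick_rate_hz` with contact duration `contact_dur_s`, so within-bout gaps
#' are below 1 s and between-bout gaps above 1 s by construction.
#'
#' @param config A [synth_config()]; only `lick_params`, `duration_s` and
#'   `seed` are used.
#' @return An interval [event_series()] labeled `"lick"`, with the planted
#'   bout intervals in attribute `"bouts"`.
#' @export
generate_lick_train <- function(config) {
  if (!inherits(config, "synth_config"))
    ff_stop("ff_param_error", "'config' must be a synth_config")
  lp <- config$lick_params
  with_local_seed(config$seed + 104729L, {
    if (lp$bout_rate_hz <= 0 || lp$lick_rate_hz <= 0)
      return(structure(event_series(start_s = numeric(0), end_s = numeric(0),
                                    label = "lick"),
                       bouts = data.frame(start_s = numeric(0),
                                          end_s = numeric(0))))
    n_bouts <- stats::rpois(1, lp$bout_rate_hz * config$duration_s)
    if (n_bouts == 0)
      return(structure(event_series(start_s = numeric(0), end_s = numeric(0),
                                    label = "lick"),
                       bouts = data.frame(start_s = numeric(0),
                                          end_s = numeric(0))))
    starts <- sort(stats::runif(n_bouts, 0, config$duration_s))
    period <- 1 / lp$lick_rate_hz
    on_s <- off_s <- numeric(0)
    b_start <- b_end <- numeric(0)
    last_end <- -Inf
    for (s in starts) {
      if (s <= last_end + 1.5) next  # keep between-bout gaps > 1 s
      n_licks <- 1L + stats::rpois(1, max(0, lp$licks_per_bout_mean - 1))
      ons <- s + (seq_len(n_licks) - 1L) * period
      offs <- ons + lp$contact_dur_s
      keep <- offs <= config$duration_s
      if (!any(keep)) next
      ons <- ons[keep]; offs <- offs[keep]
      on_s <- c(on_s, ons); off_s <- c(off_s, offs)
      b_start <- c(b_start, ons[1L]); b_end <- c(b_end, offs[length(offs)])
      last_end <- offs[length(offs)]
    }
    structure(event_series(start_s = on_s, end_s = off_s, label = "lick"),
              bouts = data.frame(start_s = b_start, end_s = b_end))
  })
}
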