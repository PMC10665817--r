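---
title: "fiberflow: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{fiberflow: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(fiberflow)
```

This vignette explains the models and procedures the package implements,
the parameters that matter, the design choices made where the design was
genuinely open, and what the synthetic-data validation does and does not
demonstrate about real recordings.

## 1. The signal model

A frame-multiplexed photometry rig interleaves excitation LEDs frame by
frame: at a 20 Hz camera rate with two LEDs (415 nm isosbestic reference,
470 nm calcium-dependent signal), each channel is a 10 Hz series. We model
each deinterleaved channel as

    raw(t) = drift(t) + g · artifact(t) + calcium(t) [signal channel only] + noise(t)

where `drift` is slow photobleaching, `artifact` is a motion component
shared across excitation wavelengths with channel gain `g`, and `calcium`
is the indicator signal of interest. The shared-artifact assumption is the
premise of reference-based correction: whatever bends the fiber affects
both wavelengths, while only the signal channel sees calcium.

### The zdF/F chain

`compute_zdff()` runs, in order: smoothing, airPLS baseline subtraction,
standardization, reference-to-signal fitting, subtraction.

**Smoothing** (`smooth_trace()`): centered moving average of
`smooth_window_s` (default 1 s, i.e. 11 samples at 10 Hz, symmetric so
zero phase; edges use shrinking windows so length and DC are preserved).
A zero-phase 2nd-order Butterworth low-pass (`lowpass_cutoff_hz`, applied
forward-backward) is the alternative; the moving average is the default
because it is the common choice in photometry preprocessing and has no
tuning beyond the window.

**Baseline removal** (`airpls_baseline()`): adaptive iteratively
reweighted penalized least squares. Each iteration solves the weighted
Whittaker problem `min Σ wᵢ(yᵢ − zᵢ)² + λ Σ (Δ²z)ᵢ²` (sparse Cholesky via
the Matrix package), then reweights: points above the running baseline get
weight 0, points below get `wᵢ = exp(iter·|dᵢ|/Σ|d⁻|)`, with the two
endpoints anchored at `exp(iter·max|d⁻|/Σ|d⁻|)`; iteration stops when the
summed magnitude of negative residuals falls below `tol · Σ|y|` (default
1e-3) or at `max_iter` (default 50). The asymmetric weighting is what
keeps calcium transients from pulling the baseline up.

The penalty default is `λ = 1e9`. The baseline's effective timescale is
roughly `λ^(1/4)` samples — about 18 s at 10 Hz — chosen to sit between
the dynamics we must preserve (multi-second, bout-locked calcium
elevations) and the dynamics we must remove (photobleaching with
time constants of minutes). Small penalties (1e4 and below) make the
baseline flexible at the ~1 s scale, where it visibly absorbs sustained
calcium elevations; this is easy to demonstrate with the synthetic
generator by comparing the fitted baseline to the known drift.

**Standardization** (`standardize()`): z-score to mean 0, sd 1. Inputs
with sd below `sd_floor` (default 1e-8) return zeros and a degenerate
flag instead of dividing by ~0.

**Reference fit** (`fit_reference()`): non-negative L1-regularized least
squares with a single predictor,
`min (1/2n)Σ(z_S − a·z_R − b)² + α|a|`, `a ≥ 0`. With one predictor the
solution is closed-form (soft-thresholded, clipped least squares); a
box-constrained numerical minimizer serves as the independent oracle in
the tests. `α` defaults to 1e-4 — near-unregularized but able to zero the
slope when the reference is anti-correlated. The non-negativity constraint
encodes that artifacts enter both channels with the same sign.

**Subtraction**: the standardized reference is linearly interpolated onto
the signal's timestamps (the two channels sit on offset grids by
construction of interleaving) and the fitted reference is subtracted. With
`α = 0` the result is exactly mean-free.

The whole chain is invariant to affine rescaling of either channel's raw
camera units, and the slope is fitted once per trace: fitting per segment
would track slow gain changes but risks absorbing real signal; whole-trace
fitting is the simpler, more conservative choice.

## 2. Behavioral quantities

- `speed_from_coords()`: two-point speed
  `√((x₁−x₀)² + (y₁−y₀)²)/(t₁−t₀)`, assigned to interval end times.
- `mobility_score()`: per-session min-max scaling of speed to [0, 1].
  Scaling is per session (not per animal across sessions) because it
  exists to make different tracking setups comparable; a constant-speed
  session is flagged degenerate.
- `detect_bouts()`: immobility = maximal runs with score strictly below
  0.1 lasting at least 2 s (a sample exactly at 0.1 counts as mobile; a
  run's duration extends to the first supra-threshold sample). Mobility
  bouts are the complement, so bouts tile the session by construction.
- `detect_consumption()`: lick contacts separated by gaps < 1 s merge
  into one event; merged events shorter than 0.5 s are discarded. The
  operation is idempotent: consumption intervals re-enter unchanged.
- `select_events()`: the four peri-event kinds — mobility onsets,
  immobility onsets (interior bout boundaries), and random times inside
  mobility/immobility bouts. Random times keep at least half a window
  from bout and session edges so every peri-event trace is complete; this
  clearance rule is ours (any complete-coverage rule would do, this one
  never biases window content).

## 3. Peri-event statistics

`extract_perievent()` interpolates each event-centered segment onto a
uniform relative-time grid (default: the trace's own rate). Trials with
incomplete coverage are dropped and counted, never padded — padding would
silently bias trial means near session edges. No additional per-trial
baseline subtraction is applied by default (zdF/F is already
standardized); `trial_mean()` reports mean and SEM with SEM defined as
sample sd / √n (the universal convention; a single trial yields zero SEM
plus a flag). `perievent_auc()` integrates trapezoidally over a named
window and divides by the window length, interpolating the window
endpoints so off-grid bounds are exact for piecewise-linear curves; a
constant c therefore yields exactly c. The named windows per test
(`window_table()`): airpuff {baseline (−2,−1), airpuff (0,1.5)},
consumption {baseline (−2,−1), onset (−0.5,1), drinking (2,4)}, mobility
{immobile (−3,−1), pre-onset (−1,0), onset (0,1), mobility (1,3)},
avoidance {baseline (−2,−1), CS (0,8), crossed (8,11)}.

## 4. Correlation and lag analysis

`session_pearson()` resamples both series onto the grid of the
lower-rate trace before correlating. `classify_events()` computes, per
event, the Pearson correlation over the 6-s event-centered window and
classifies it positive (`p < 0.001` and `r > 0.6`), negative
(`p < 0.001` and `r < −0.6`), or uncorrelated. The window is centered
(−3 to +3 s) to match the mobility-onset AUC span. P-values use the
standard t-transform of r; peri-event samples are autocorrelated, so
these p-values are optimistic — the thresholds are configurable, and the
classifier's false-positive rate is checked empirically against the
independence null in the tests (it sits well below the nominal level
because the classification also requires |r| > 0.6 at n ≈ 60).

`crosscorr_lag()` evaluates, for each lag ℓ on a symmetric grid (default
±2 s in one-sample steps), the correlation between the calcium trace
shifted to `t + ℓ` and mobility at `t` over the event window. Sign
convention: if mobility reproduces calcium half a second later, the
maximum sits at ℓ = −0.5 — negative lags mean calcium leads. Ties are
broken toward the smallest |ℓ| so that flat correlation plateaus report
the most conservative lead. Both per-event lags-of-maximum and the
event-averaged correlation curve are returned: per-event lags feed
animal-level summaries, while the averaged curve is far more stable when
single events are noisy.

## 5. Optogenetics metrics

`preference_score()` implements
`(time ON − time OFF)/total`, with OFF = session − ON exactly as the
formula prints; a three-state variant (corridor time counting to
neither chamber) can be built by passing the complement occupancy
explicitly, but the printed two-state formula is the default for exact
reproducibility. `epoch_metrics()` detects bouts once on the whole
session and attributes each to the laser condition of the epoch
containing its onset (bouts straddling a boundary are not split —
attribution by onset keeps bout durations intact). `consumption_metrics()`
reports mean event duration, mean inter-event interval (undefined and
flagged with fewer than two events), count, and total duration;
`normalize_to_baseline()` divides each stimulation-session metric by the
mean of the last pre-session and the post-session, flagging zero
baselines rather than throwing.

## 6. The synthetic generator and what it validates

`generate_session()` draws: alternating immobility/mobility bouts with
shifted-exponential durations (means 10 s and 8 s, minima 3 s and 2 s);
a mobility waveform with 0.3-s linear ramps at transitions, converted to
a noisy speed and min-max scaled; double-exponential photobleaching
drift; random-sign biexponential motion artifacts (Poisson rate 0.5 Hz,
amplitude 10 camera units ≈ 2× the calcium amplitude, reference gain
0.5) shared across channels; calcium = a bout-coupled component (the
clean mobility waveform time-shifted by `coupling_lag_s` and scaled by
`coupling_amp = 5`) plus background Poisson transients with a
difference-of-exponentials kernel (rise 0.2 s, decay 1 s, GCaMP6s-like);
white per-frame noise (`noise_sd = 2.5`, half the transient peak). The
coupled component being an exact time-shifted copy of the mobility
waveform is deliberate: it makes the cross-correlation lag identifiable,
so lag recovery tests the estimator rather than the shape mismatch
between an arbitrary kernel and the behavior waveform. Every latent
(transient times, drift, artifact, bout plan, true lag, lick bouts) is
returned as ground truth, and identical configs give bit-identical
sessions.

Artifact parameters place the default session in the strong-artifact
regime: artifacts at 0.5 Hz, twice the calcium amplitude. That is the
regime reference-based correction exists for, and it is what the
suppression checks assume — with rare or tiny artifacts the fitted slope
is noise-limited and suppression is bounded by the artifact fraction of
the reference variance, a property of the estimator, not a defect.

**Validation design.** The test suite checks, among others: clean-signal
recovery (correlation of zdF/F with the known calcium component ≥ 0.8 on
a default 600-s session) and ≥ 50% artifact-correlation suppression;
exact recovery of planted bouts and lick bouts including one-sample
boundary cases around every threshold; AUC exactness on constants;
classifier calibration on 10⁴ independence-null events; and lag recovery.
The lag-recovery session (900 s, ~48 onsets, lag −0.4 s) uses reduced
nuisance (noise at 0.25× the transient peak, artifact amplitude 2, no
background transients): per-event argmax lags are heavy-tailed when
in-window SNR is low — single events then peak anywhere in ±2 s — so a
calibration check under full nuisance would measure noise, not bias. The
estimator's bias is what the check certifies (it is zero to well within
one 0.1-s lag step); robustness to nuisance is certified separately by
the suppression checks.

**What passing does not show.** The generator's mobility is a clean
two-state process; real behavior has graded speeds, tracking dropouts,
and artifacts correlated with movement (ours are independent by
construction, which if anything makes artifact suppression harder to
fake and easier to measure). Bleaching is a fixed double exponential;
real drift can include lamp warm-up and focus shifts. No spike-to-calcium
biophysics is modeled, and CS/shock schedules are supplied, not learned.
Recovery on this generator certifies the estimators' correctness and
calibration, not their performance envelope on any particular rig.

## 7. Numerical and I/O choices

- Timestamps come from the acquisition file and are never re-derived from
  frame indices; frames before the first complete LED cycle are kept
  (alignment is timestamp-based, so partial cycles are harmless).
- LED-state codes are the bitmask 1/2/4 for the first/second/third
  declared channel.
- All cross-grid evaluation is linear interpolation; extrapolation is an
  error, and peri-event or lag windows without full coverage exclude the
  event with a warning count.
- The session store is a directory of CSVs plus a JSON manifest carrying
  a layout version and per-group class metadata; round-trips restore
  classes and values to written precision, and all writers format
  numbers deterministically so identical runs are byte-identical.
- Errors are classed conditions (`ff_param_error`, `ff_data_error`,
  `ff_format_error`, `ff_key_error`, `ff_range_error`, ...) naming the
  offending field, row, or group.
- Problem sizes in the test suite — 120–900 s synthetic sessions, 10⁴
  null events, 500-sample oracle comparisons — were chosen as the
  smallest sizes at which each property is stably measurable.

## 8. Known limitations

- Pearson p-values ignore autocorrelation (by design, to match standard
  practice); treat per-event p-values as a ranking device, and rely on
  the empirical null calibration.
- One reference, one slope: no multi-reference regression, hemodynamic
  correction, or time-varying gain tracking.
- The lag-of-maximum statistic quantizes to the lag grid; sub-sample
  precision would need parabolic interpolation around the maximum, which
  is deliberately not applied to keep the statistic simple and
  tie-breaking transparent.
- `read_dlc_coords()` ignores the likelihood column by default; no
  filtering of low-confidence tracking points is applied.

## 9. A complete run

```{r pipeline, eval = FALSE}
report <- run_pipeline(run_config(seed = 1), "out_dir")
str(report$stages$correlate)
```

The report records the configuration hash, seed, package version, and
per-stage summaries (fit coefficients, bout/event counts, classification
fractions, lag summaries), and the session store under `out_dir/session`
holds every intermediate product.
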