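# fiberflow

Analysis toolkit for multi-LED fiber photometry recordings with
synchronized behavior: signal correction (zdF/F), behavioral event
detection, peri-event statistics, correlation/lag analysis, and
optogenetics behavioral metrics — plus a synthetic-session generator with
known latent structure so the whole chain can be validated by parameter
recovery.

## The problem

Fiber photometry measures bulk calcium-indicator fluorescence (e.g.
GCaMP6s) through an implanted optical fiber while an animal behaves
freely. Raw traces are contaminated by photobleaching drift and by motion
artifacts from fiber bending. In frame-multiplexed rigs a camera running
at 20 Hz alternates excitation LEDs (415 nm isosbestic reference, 470 nm
calcium-dependent signal), so each channel is sampled at 10 Hz and the
reference captures artifacts without calcium dependence. Typical
scientific questions downstream: does pathway activity rise at movement
onset, does it lead or lag behavior, and does stimulating the pathway
change movement?

## The method

The standardized dF/F (**zdF/F**) chain, for signal trace *S(t)* and
reference trace *R(t)*:

1. smooth both traces (centered moving average, default 1 s; a zero-phase
   Butterworth low-pass is available);
2. flatten each by subtracting an **airPLS** baseline — adaptive
   iteratively reweighted penalized least squares: iterate a weighted
   Whittaker smoother with second-order difference penalty λ, zeroing the
   weights of points above the running baseline so peaks do not pull it
   up, `w_i = exp(iter·|d_i| / Σ|d⁻|)` for points below;
3. standardize each to mean 0, sd 1;
4. fit the standardized reference to the standardized signal by
   non-negative L1-regularized least squares
   (`min (1/2n)‖z_S − a·z_R − b‖² + α|a|`, `a ≥ 0`);
5. `zdF/F(t) = z_S(t) − (a·z_R(t) + b)`.

Behavior: speed `√((x₁−x₀)² + (y₁−y₀)²)/(t₁−t₀)` is min-max scaled per
session to a **mobility score** in [0, 1]; an **immobility bout** is a
run of scores `< 0.1` lasting `≥ 2 s`, mobility bouts are the complement.
**Consumption events** merge lick contacts separated by gaps `< 1 s` and
keep merged events lasting `≥ 0.5 s`. Peri-event traces are aligned to
events and summarized by normalized AUC, `AUCnorm = AUC/(t₁ − t₀)`, over
test-specific named windows (airpuff, consumption, mobility onset,
avoidance). Peri-event Pearson correlations between zdF/F and mobility
are classified as positive (`p < 0.001`, `r > 0.6`), negative
(`p < 0.001`, `r < −0.6`) or uncorrelated, and a windowed
cross-correlation locates the signed lag of maximum correlation
(negative lag = calcium leads behavior). Optogenetics readouts include
the real-time place preference score
`(time laser ON − time laser OFF)/total time`, per-epoch mobility/bout
metrics under alternating 2-min laser epochs, and consumption metrics
normalized to flanking baseline sessions.

## Worked example

Everything below runs on a synthetic session with known ground truth
(300 s, calcium leading mobility by 0.4 s):

```r
library(fiberflow)
cfg <- synth_config(duration_s = 300, seed = 1, coupling_lag_s = -0.4)
ses <- generate_session(cfg)
traces <- deinterleave(ses$recording)
zdff <- compute_zdff(traces[["470"]]$Region0, traces[["415"]]$Region0)
zdff
#> <photometry_trace> channel 470, roi Region0, 2999 samples @ 10 Hz [zdff]
#>   time 0.050 .. 299.850 s, value range [-1.747, 2.312]
attr(zdff, "fit")
#> <fit_result> slope_a = 0.669824, intercept_b = -0.000211547

bouts <- detect_bouts(ses$behavior)
table(bouts$label)
#> immobility   mobility
#>         16         16

pem <- extract_perievent(zdff, ses$events$mobility_onset, pre_s = 3, post_s = 3)
pem
#> <perievent_matrix> 15 trial(s) x 61 samples, rel time -3.00..3.00 s (1 dropped)
sapply(window_table("mobility"), function(w) perievent_auc(pem, w)$mean)
#>  immobile pre_onset     onset  mobility
#>    -0.757    -0.181     0.582     0.576

classify_events(zdff, ses$behavior, ses$events$mobility_onset)
#> <event_class_counts> 15 events: 13 positive, 0 negative, 2 uncorrelated (1 excluded)
crosscorr_lag(zdff, ses$behavior, ses$events$mobility_onset)
#> <lag_result> 15 events, mean lag at max = -0.440 +/- 0.104 s (1 excluded)
```

Reading the output: the reference fit found slope 0.67 (the shared
artifact fraction), zdF/F is elevated in the onset and mobility windows
relative to immobility (normalized AUC −0.76 → +0.58), most mobility
onsets show a positive peri-event correlation, and the lag of maximum
cross-correlation recovers the planted −0.4 s calcium lead.

The full chain also runs as one call (or from the shell via
`inst/cli/fiberflow.R`):

```r
report <- run_pipeline(run_config(seed = 1), "out_dir")
```

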