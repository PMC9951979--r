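---
title: "Methods: EMG-based reconstruction of shank angular velocity and gait events"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: EMG-based reconstruction of shank angular velocity and gait events}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

This vignette documents the modelling assumptions, parameter choices and
numerical conventions behind `emg2gait`, and what the synthetic validation
does and does not establish about real recordings.

## Signal model

The package treats walking as a quasi-periodic process observed through two
modalities: the shank angular velocity about the medio-lateral axis
(gyroscope, one channel per leg) and surface EMG of up to five bilateral
leg-muscle pairs (tibialis anterior Ta, soleus S, gastrocnemius
medialis/lateralis Gm/Gl, vastus lateralis Vl). Because muscle activation
both precedes and follows the mechanical events of the cycle, a *linear*
map from EMG to angular velocity is only plausible after two steps:

- **envelope extraction** — rectified, heavily smoothed EMG approximates
  the slowly varying activation amplitude;
- **temporal embedding** — each envelope is complemented by 21 lagged
  copies spanning −500…+500 ms in 50 ms steps, so the readout at time *t*
  sees one second of muscular context around *t*.

The readout `ŷ(t) = βᵀx̃(t)` is fitted by ordinary least squares. No
regularization is applied by default: with minutes of training data and at
most 211 features, the design is strongly over-determined, and the plain
OLS solution keeps the model interpretable as a linear filter. A ridge
penalty is available (`fit_ols(..., ridge = )`) but off by default. The
solver uses a QR factorization (`lm.fit`), falling back to an SVD
pseudoinverse on rank-deficient designs; the textbook normal-equations
form `(X̃X̃ᵀ)⁻¹X̃yᵀ` is numerically inferior and survives only as an
independent oracle in the test suite.

Left- and right-ankle targets are fitted as two independent coefficient
vectors sharing one design matrix. Both sides of every selected muscle are
always included (bilateral pairs), giving `2⁵ − 1 = 31` candidate muscle
sets of 2–10 channels.

## Preprocessing

EMG path: bandpass → rectify → decimate to 200 Hz → 200 ms moving median →
40 ms moving mean → subtract 10 s moving minimum → percentile
normalization. IMU path: nearest-neighbour upsample to 200 Hz → 100 ms
moving median → 40 ms moving mean. Streams are then aligned to the first
TTL rising edge and cropped to the annotated walking period.

Parameter choices that were genuinely open:

- **Bandpass corners 20–450 Hz, 4th-order zero-phase Butterworth.** The
  standard surface-EMG band: below 20 Hz lies motion artifact, above
  450 Hz mostly noise at a 1000 Hz sampling rate. Configurable via
  `preprocessing_config()`.
- **Decimation without an extra anti-aliasing stage.** The bandpass has
  already limited the spectrum, and the subsequent 200 ms median dominates
  any residual aliasing of the rectified signal.
- **Centred moving filters with symmetric edge truncation.** At the first
  and last `(k−1)/2` samples the window shrinks symmetrically rather than
  padding; windows in ms convert to samples as `round(ms·fs/1000)` forced
  odd. Each filter is tested against a per-window brute-force oracle.
- **Normalization order.** The amplitude normalization subtracts the 1st
  percentile and divides by the 95th percentile *of the
  baseline-subtracted signal*, per channel and per recording — the reading
  in which subtraction precedes division. Percentiles use linear
  interpolation between order statistics (`quantile` type 7). Because
  percentiles are estimated on the full recording before cropping, the
  95th percentile of the *cropped* walking segment sits slightly above 1;
  the effect shrinks with trial length and stays within ±0.02 for trials
  of a minute or more.
- **Walking bounds are required metadata.** On/offsets of the walking
  period are annotations, not detected automatically; automatic walk-bout
  detection is a different problem and out of scope.

## Event extraction

Swing peaks (SWP) are local maxima with amplitude ≥ 150 °/s and ≥ 0.7 s
separation. Conventions where the rule set under-determines behaviour:

- *local extremum* means strictly greater/less than both neighbours;
  plateaus resolve to their first sample;
- when two candidate peaks violate the separation, the higher wins, ties
  to the earlier;
- *peak height* is absolute amplitude, not prominence (a prominence mode
  would change behaviour only on drifting baselines, which the moving-
  minimum stage removes for EMG and which gyroscopes do not exhibit);
- cycle-fraction windows (10–45 % for HC, 55–90 % for TO) map to sample
  indices rounding toward the interior, so candidates are strictly inside
  the cycle;
- when a sub-interval contains no interior local minimum, its global
  minimum is used — the first occurrence for HC ("earliest"), the last for
  TO ("latest");
- a sign-inverted sensor is handled by `event_config(invert_av = TRUE)`.

Phase segmentation uses half-open intervals: stance from each HC
(inclusive) to the next TO (exclusive), swing from each TO to the next HC;
samples before the first and after the last defining event are undefined.
The same convention applies to true and predicted events, so segmentation
metrics are not biased by the boundary rule.

## Evaluation

- **Event matching.** The specification of a match is symmetric and local:
  a true and a predicted event may pair iff they are < 600 ms apart, each
  event at most once. Among the tolerance-respecting assignments the
  implementation picks one maximizing the number of pairs and, among
  those, minimizing the total |Δt|, via a non-crossing dynamic program
  over the two sorted lists (an optimal assignment can always be reordered
  to be non-crossing without losing pairs or increasing total |Δt|).
  Greedy nearest-pair matching — the simpler alternative — provably drops
  pairs on dense event configurations (e.g. true events at 0 and 0.5 s,
  predictions at 0.45 and 1.04 s), which the brute-force assignment oracle
  in the test suite exposes; on realistically separated gait events (one
  event per ~1.1 s cycle, tolerance 0.6 s) the two coincide.
- **Displacement** is signed predicted-minus-true (positive = late);
  summaries use absolute displacements, per-trial medians with IQRs across
  trials.
- **F1** of the swing/stance series takes swing as the positive class; the
  macro average over both classes is reported alongside.
- **Error rates** are pooled across trials from event counts (total misses
  over total true events), never averaged per-trial rates, so trials with
  few events do not dominate.
- **Correlograms** report, per lag τ, the correlation of `x(t+τ)` with
  `y(t)` — the embedding's own convention, so EMG activity that *lags
  behind* the angular velocity by δ peaks at τ = +δ. Significance uses the
  t-distribution of the correlation with Bonferroni correction over a
  family of 420 tests (210 features × 2 target sides) by default;
  configurable because the appropriate family depends on how many muscles
  and sides an analysis actually examines.

## Synthetic cohort generator

The generator's role is to provide *known ground truth* under realistic
statistical structure, not biomechanical fidelity.

- **Angular velocity** is a piecewise cubic "smoothstep" interpolation
  between knots with zero slope: the swing peak at each cycle start, the
  HC trough at 25 % of the cycle, a small mid-stance hump, the TO trough
  at 70 %. Extrema are therefore strict and analytically placed, which is
  what closed-loop event-recovery tests need. Defaults: 1100 ms nominal
  cycles (within the 1045–1140 ms range of self-paced walking in mildly
  affected parkinsonian cohorts), 250 °/s swing peaks, 15 ms MAD duration
  jitter (reported variability is 10–30 ms), legs in antiphase.
- **EMG** is a zero-mean carrier amplitude-modulated by the activation
  envelope. In the realistic *burst mode* the carrier is broadband
  Gaussian noise and envelopes are raised-cosine bursts phase-locked to
  the cycle (Vl at heel contact, Ta in swing, the plantar flexors in
  stance); rectification and smoothing then recover the envelope only up
  to ~10 % per-sample estimation noise — exactly as with real surface
  EMG. In *linear ground-truth mode* the envelope is an exact affine
  function of the leg's angular velocity delayed by a muscle-specific lag
  (Vl +150 ms), and the carrier is a deterministic 90 Hz sinusoid: at the
  200 Hz decimated rate its phase orbit is a fixed 20-point cycle, so the
  200 ms moving median demodulates it to an exact constant factor and the
  recovered envelope remains an exact affine image of the delayed angular
  velocity. This mode is what makes near-perfect recovery testable; a
  stochastic carrier would impose an irreducible noise floor.
- **Cohort defaults** (`simulation_config()`): 6 patients × 4 trials ×
  180 s — the scale of a small clinical gait study — with patient-level
  gain variability (30 %), burst-timing shifts (3 % of the cycle) and
  swing-amplitude variability (8 %), making leave-one-patient-out
  generalization non-trivial. All randomness flows through one seed;
  identical configurations reproduce identical files.
- **What it does not emulate:** gait non-stationarity (freezing, turning,
  fatigue), electrode lift-off and motion artifacts, muscle crosstalk,
  sensor drift, or genuinely nonlinear EMG-kinematics coupling. Passing
  the synthetic suite therefore demonstrates correctness of the pipeline's
  operations and its statistical machinery, not clinical performance on
  patients; the guardrail thresholds in the end-to-end tests (held-out
  median r > 0.95, F1 > 0.9, displacements < 60 ms, pooled FNR < 0.02 in
  linear mode) characterize the pipeline under known-linear conditions.

## Numerical conventions and degenerate inputs

- Common clock: 200 Hz, sample *i* (1-based) at time `(i−1)/200` s; lag
  grids must land on integer samples (the defaults give 10-sample steps).
- Embedding boundaries: samples whose ±500 ms window exits the trial are
  excluded from fitting and predicted as `NA`; training trials are
  embedded separately so no window straddles a trial seam. Events falling
  in these half-second margins are the dominant source of residual missed
  events in end-to-end runs.
- Constant channels make the percentile normalization and the Pearson
  correlation undefined; both raise informative errors rather than
  returning `NaN`. Zero-denominator FDR/FNR are `NA` markers, not errors.
- Fewer than two swing peaks yield an empty cycle list (not an error);
  fewer than three are insufficient for cycle statistics (an error).

## Problem sizes in the shipped checks

Unit tests run on seconds-long signals; the end-to-end LOPO check uses 6
patients × 2 trials × 120 s, and `scripts/acceptance.R` the full default
cohort (6 × 4 × 180 s), sizes chosen to exercise every stage at a small
multiple of the embedding span while keeping a complete run in the
low minutes on one CPU.

## Known limitations

- The regression is strictly linear; systematically nonlinear
  EMG-kinematics relationships (e.g. saturating activations) are fitted
  only in the least-squares sense.
- Amplitude calibration of reconstructed traces depends on the percentile
  normalization transferring across patients; a patient whose swing
  amplitude departs far from the training cohort shifts predicted peaks
  relative to the fixed 150 °/s rule.
- Event extraction assumes the one-positive-peak-per-cycle morphology of
  medio-lateral shank angular velocity in forward walking; it is not
  intended for turning, shuffling or stair gait.
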