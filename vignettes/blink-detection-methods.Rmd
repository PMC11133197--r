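---
title: "Detecting blinks in eye-openness signals: methods and design notes"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Detecting blinks in eye-openness signals: methods and design notes}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

## Signals and assumptions

`blinkeo` works on two per-sample signals from video-based eye trackers:

* the **eye-openness (EO) signal** — the distance in mm between the upper
  and lower eyelids (the diameter of the largest sphere that fits between
  them), which remains measurable even when the eye is closed; and
* the **pupil-size (PS) signal** — the pupil diameter in mm, which is
  reported invalid while the eyelid occludes the pupil.

A blink appears in the EO signal as a smooth dip: a fast, high-velocity
descent of the lid, an optional closed interval, and a slower re-opening.
The detector assumes (i) timestamps are strictly increasing and close to
regular at the nominal rate, (ii) invalid samples are flagged by the
tracker and carry no usable value, and (iii) within one trial the resting
("fully open") eyelid level is stable enough for its median to serve as a
reference. It makes no assumption about absolute levels: all amplitude
rules are relative to the trial median and all velocity rules are relative
to the robust dispersion of the observed velocity, so detection is
invariant to a rescaling of the signal.

## The EO detector, step by step

```{r eval = FALSE}
library(blinkeo)
events <- detect_eo_blinks(recording, eye = "left", detection_settings())
```

1. **Gap repair.** Invalid runs shorter than `gap_fill_ms` (40 ms) with
   valid samples on both flanks are linearly interpolated. Linear
   interpolation is the conventional choice for short eye-tracking
   dropouts; edge-touching gaps have no flanking support and are never
   extrapolated.
2. **Smoothing.** A Savitzky–Golay filter (`filter_len_ms` = 25 ms, order
   2) is used *only* to locate closure minima. The window length in
   samples is `round(filter_len_ms * fs / 1000)` forced odd by
   incrementing (15 samples at 600 Hz); a centered odd window is required
   for an unbiased local fit.
3. **Closure candidates.** Local minima of the smoothed signal qualify
   when their topographic prominence reaches
   `min_amplitude_frac * fully_open` (10% of the EO median) and when
   minima are at least `min_duration_ms` apart (the deeper minimum wins a
   conflict). These peak-finder thresholds only prune candidates early;
   inclusion is finally decided by the step-7 rules computed on the
   unfiltered signal.
4. **Velocity.** Eyelid velocity is the Savitzky–Golay first derivative
   (same window, order 2) of the **unfiltered**, gap-repaired signal,
   scaled to mm/s. The differentiator itself supplies the noise
   suppression; smoothing before differentiation would low-pass the
   signal twice and bias peak velocities downward. Velocity is signed
   (closing negative); thresholds compare `|v|`.
5. **Onset/offset expansion.** From each minimum the detector scans
   backward and forward until `|v|` settles below
   `T_vel = onset_vel_mad_factor * MAD(v)` (3 MADs) on the far side of
   the fast phase. `MAD(v)` is the raw median absolute deviation
   (`mad_raw()`, no 1.4826 consistency constant) over all valid velocity
   samples of the whole trial — a single threshold per series, appropriate
   for trials of roughly a minute. The MAD is computed on signed
   velocities; deviation about the median absorbs the sign asymmetry.
6. **Kinematics.** Openness at onset, offset and minimum, the closing
   amplitude (onset minus minimum), opening amplitude (offset minus
   minimum), and the peak speed and its time within each phase are read
   from the unfiltered signal.
7. **Rejection.** A candidate is kept only if
   `max(closing_amp, opening_amp) >= min_amplitude_frac * fully_open`,
   `duration >= min_duration_ms` (30 ms), and
   `min(peak_closing_vel, peak_opening_vel) >=
   min_peak_vel_mad_factor * MAD(v)` (2 MADs). Using the *larger*
   amplitude protects blinks whose post-blink baseline is lower than the
   pre-blink one, a common feature of real lids; requiring the *lower*
   peak speed rejects slow drifts that pass on one side only.
8. **Merging.** Events separated by less than `merge_ms` (100 ms) are
   merged iteratively to a fixed point, with kinematics recomputed over
   the union.

### Numerical and degenerate-case choices

* **Scan robustness.** The closed interval between the closing and
  opening phases has near-zero lid velocity, so the outward scan must
  first cross a sub-threshold stretch before traversing the fast phase.
  With tracker noise of realistic magnitude, isolated samples inside the
  closed interval occasionally graze `T_vel`; a supra-threshold run
  therefore only terminates the scan if it reaches `2 * T_vel`. Real
  closing/opening phases exceed this comfortably (their peaks sit more
  than an order of magnitude above `T_vel` for full blinks), while
  threshold-grazing noise excursions almost never do. The trade-off is
  that blinks whose peak speed lies between `2 * MAD(v)` and
  `6 * MAD(v)` — extremely slow movements barely above the rejection
  floor — may be truncated; such movements are at the edge of what a
  velocity-based detector can delimit at all.
* **Noise-free input.** On synthetic noise-free data `MAD(v)` can be
  exactly zero; `T_vel` then falls back to 1% of the largest observed
  speed so the threshold stays meaningful. On any realistic recording the
  MAD term dominates and the floor is inert.
* **Clipping.** A scan that reaches the series edge or an invalid
  velocity sample stops there and flags the event `clipped`; if this
  happens before any fast phase was seen the candidate collapses to a
  point and is dropped by the duration rule. A closure bottom interrupted
  by unrepairable data loss yields no candidate in the first place
  (minima are searched within valid segments), reproducing the known
  failure mode of peak-based detection under loss concentrated in the
  re-opening phase.
* **Validity propagation.** Any smoothed or differentiated sample whose
  window overlaps an invalid source sample is itself invalid; the filters
  never manufacture values across data loss. Filter edge samples use the
  off-center evaluation of the first/last full window.
* **Phase labels.** The phase from onset to minimum openness is labeled
  *closing* and the phase from minimum to offset *opening* — closing
  precedes opening physiologically, and closing is the faster phase.
  Descriptions of velocity-based delimitation sometimes attach the two
  labels in the opposite order when enumerating "maximum velocity before
  / after the peak"; the package follows the physiological order.
* **Fully open level.** The median is computed after gap interpolation on
  the unfiltered series. At the sub-percent loss levels typical of EO
  signals the difference between before and after is negligible.

## The PS comparison detector

`detect_ps_blinks()` implements the traditional detector: interpolate
gaps `< 40 ms`, take each remaining maximal invalid run as one blink,
merge runs closer than 100 ms. Events are half-open
`[first invalid, first valid after)`, so an interior gap of *k* samples
lasts exactly `k/fs` — an unambiguous sampling convention for a quantity
whose offset the data do not define more precisely. Optional
physiological exclusions (`ps_options()`) mark non-positive diameters
and/or values outside 2–7 mm invalid, plus a 50 ms margin around each
violating run; optional duration bounds (e.g. 30 ms–3 s) are off by
default because the plain three-step detector does not use them.
Statistical-outlier exclusion (z-scores on diameter) is deliberately not
implemented; its windowing is under-specified and it belongs to the
refinement literature rather than to the baseline detector.

## Evaluation utilities

`match_events()` pairs two event streams one-to-one: a pair must overlap
in time; the largest overlap wins; pairing is resolved greedily in
reference onset order with ties broken toward the earlier test onset.
The overlap requirement and one-to-one constraint are the essence of
established event-matching procedures for eye-movement classifiers; the
exact tie-break is rarely restated in the literature, so the rule above
is *declared*, not inferred. The event-based F1 is
`2*TP/(2*TP + FP + FN)`, with `F1 = 1` for two empty streams. Sample
standard deviations (n−1) are used throughout, as per-trial event counts
are small.

`quality_report()` operationalizes **data loss** as invalid samples over
all samples and **RMS-S2S** as the root mean square of differences
between consecutive samples where both are valid. The whole series is
used, including blink periods — eyelid motion genuinely inflates EO
RMS-S2S, and the metric is reported as defined rather than on a
motion-free subset.

## What the simulator emulates — and what it does not

`simulate_recording()` produces 60 s binocular recordings at 600 Hz with
blinks prompted at 1 Hz (±50 ms uniform onset jitter), emulating a
prompted-blink protocol. Each blink is a half-cosine descent (63 ms), a
closed plateau (50 ms at 0.73 mm), and a half-cosine ascent (138 ms) from
an 8.75 mm pre-blink baseline to an 8.16 mm post-blink baseline, with a
slow linear ramp back to baseline between blinks. The half-cosine family
is C¹, parameter-sparse, and yields the fast-closing/slow-opening
peak-velocity asymmetry of real blinks; it is a stand-in, not a
physiological lid model. Channel noise is white Gaussian with per-sample
SD `rms/√2`, so a blink-free stretch shows the target RMS-S2S in
expectation (defaults 0.200 mm EO, 0.004 mm PS — representative
tracker-precision magnitudes). The pupil (4 mm) is valid only where the
noise-free aperture is at least the pupil diameter: a sphere between the
eyelids smaller than the pupil implies partial occlusion. That threshold
is a geometric idealization and is configurable. Extra, blink-unrelated
loss can be injected as geometrically distributed runs
(`inject_data_loss()`), emulating tracking difficulty at the edge of the
head box.

By construction, each blink's PS-detectable span is strictly inside its
EO span, so EO blinks bracket PS blinks and are longer — the qualitative
pattern real comparisons show. The simulator does **not** generate the
pre/post-blink pupil-size dip artifact of some high-speed trackers (the
baseline PS detector does not use it), eyelid–saccade interactions,
head-motion-dependent noise, or blink-to-blink amplitude variability
beyond the onset jitter. Passing the closed-loop tests therefore shows
that the algorithms are correct and well-calibrated for clean,
waveform-typical blinks at realistic noise; it does not certify behavior
on pathological lids, partial micro-blinks, or non-stationary noise.

## Test problem sizes

The closed-loop properties are exercised at the simulator's native study
conditions (60 s × 600 Hz × 1 Hz blinks): exact recovery on ten seeds,
EO-vs-PS bracketing on twenty recordings (~1200 matched blinks), and a
loss/agreement Spearman correlation over twenty seeds × six injected
loss levels (0–40%). Filter correctness is checked against a brute-force
per-window least-squares oracle on one hundred 2 s series, and the MAD
against its textbook definition on one thousand random vectors. These
sizes give stable statistics while keeping the default test run fast.

## Known limitations

* Blinks are detected per eye; no binocular fusion is attempted.
* No sub-classification into full/partial/twitch blinks — the event table
  carries the kinematic fields needed to build such schemes downstream.
* The detector targets offline analysis of complete trials (`MAD(v)` is a
  whole-trial statistic); it is not a streaming algorithm.
* Defaults are tuned for 600 Hz; other rates work (window lengths are
  specified in ms) but have not been characterized systematically.
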