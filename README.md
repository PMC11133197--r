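# blinkeo

Blink detection and characterization from eye-openness signals.

## The problem

Blinks — the brief closing and re-opening of the eyelids — are a workhorse
measure in research on drowsiness, workload, cognition and oculomotor
control. With video-based (pupil/corneal-reflection) eye trackers, blinks
are traditionally inferred *indirectly*: while the eyelid covers the pupil
the tracker reports invalid samples, and runs of data loss in the
pupil-size (PS) signal are taken as blinks. That proxy misses the parts of
a blink where the lid is moving but the pupil is still visible, cannot
measure eyelid kinematics at all, and confuses tracking dropouts with real
blinks.

Some trackers now export an **eye-openness (EO) signal**: the per-sample
distance, in millimeters, between the upper and lower eyelids (the diameter
of the largest sphere that fits between them). `blinkeo` detects blinks
directly in this signal and reports their full kinematics — onset, offset,
minimum openness, closing/opening amplitudes, and peak closing/opening
velocities — alongside a faithful implementation of the traditional
PS data-loss detector for comparison, event-matching/F1 evaluation
utilities, standard data-quality metrics, and a synthetic-recording
simulator with ground truth so that the whole chain can be validated
without recorded data.

## The algorithm

For an EO series sampled at rate $f_s$ (the defaults target 600 Hz):

1. Interpolate data-loss gaps shorter than 40 ms (linear).
2. Smooth the signal with a Savitzky–Golay filter (25 ms window, order 2).
3. Find candidate closures: local minima of the smoothed signal with
   topographic prominence of at least 10% of the *fully open* level — the
   median of the EO signal.
4. Compute eyelid velocity $v$ from the **unfiltered** signal with a
   Savitzky–Golay differentiator (25 ms, order 2).
5. From each closure minimum, scan backward/forward until $|v|$ settles
   below the adaptive threshold
   $T_{vel} = 3\cdot\mathrm{MAD}(v)$,
   where MAD is the raw median absolute deviation (no scaling constant).
   These stopping points are the blink onset and offset.
6. Read kinematics from the unfiltered signal: openness at
   onset/offset/minimum, closing and opening amplitudes, and peak phase
   speeds $\max|v|$ over the closing and opening phase.
7. Reject candidates with amplitude $< 10\%$ of fully open, duration
   $< 30$ ms, or a lower phase-peak speed $< 2\cdot\mathrm{MAD}(v)$.
8. Merge blinks separated by less than 100 ms.

The PS comparison detector interpolates gaps `< 40 ms`, takes each
remaining run of invalid samples as a blink, and merges runs closer than
100 ms; optional physiological exclusions (non-positive diameters, bounds
such as 2–7 mm with a 50 ms margin) are available.

## Worked example

```r
library(blinkeo)

sim <- simulate_recording(sim_config(seed = 1))   # 60 s, 600 Hz, 1 Hz blinks
eo_events <- detect_eo_blinks(sim$recording, eye = "left")
ps_events <- detect_ps_blinks(get_series(sim$recording, "ps", "left"))

match_events(eo_events, ps_events)
#> <match_result> TP=60 FP=0 FN=0 F1=1.0000

head(eo_events[, c("onset_t", "duration", "closing_amp",
                   "peak_closing_vel", "peak_opening_vel")], 3)
#>     onset_t  duration closing_amp peak_closing_vel peak_opening_vel
#> 1 0.2233333 0.2450000    8.340981         200.2843         88.62974
#> 2 1.2333333 0.2483333    8.312219         201.0643         90.31622
#> 3 2.2533333 0.2516667    8.377260         200.9575         86.36090

quality_report(get_series(sim$recording, "eo", "left"))
#> <quality_report> n=36000, loss=0.00%, RMS-S2S=0.2116 mm
```

The detector finds all 60 simulated blinks (event F1 = 1.0 against both
the ground truth and the PS detector). Blink durations average ~0.25 s
with ~8.3 mm closing amplitude; the closing phase peaks around 200 mm/s
(about 1000 deg/s via `mm_to_deg()`), more than twice the opening peak —
the characteristic fast-closing/slow-opening asymmetry. EO blinks start
~40 ms earlier and end ~67 ms later than the corresponding PS data-loss
blinks, because the eyelids move before and after the pupil is occluded.
The EO channel's RMS sample-to-sample noise is recovered at the simulated
0.2 mm level.

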