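---
title: "Methods: beat-segmented arm movement biomechanics in armbeat"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: beat-segmented arm movement biomechanics in armbeat}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(armbeat)
```

## The measurement problem

Competitive Taijiquan arm manipulation is judged partly on movement
amplitude and on "braking" — the athlete's ability to arrest a fast lift
exactly on the metronome beat. armbeat quantifies both from a single hand
marker per side, plus the accompanying muscle-activation pattern from
eight surface-EMG channels, and compares two skill groups (A and B). The
protocol fixes two movement combinations: an 8-beat sequence of front, up,
side and down lifts (symmetric around mid-sequence, so beats 1/7, 2/6, 3/5
and 4/8 repeat the same actions) and a 4-beat sequence alternating a
chest-cross connecting action (beats 1 and 3) with side lifts to ±45°
elevation. Tempo is 120 beats/min, so every beat lasts 0.5 s.

## Kinematic model

**Track length.** Movement amplitude is indexed by the action-track
length: the summed point-to-point Euclidean distance of the sampled hand
path, in 3D and projected onto the three coordinate planes. Under the
package's axis convention (x mediolateral, y anteroposterior, z vertical)
the XY projection is the horizontal plane, XZ the frontal plane and YZ the
sagittal plane. Since projection can only shorten a path, every plane
length is bounded by the 3D length; this, with a brute-force oracle,
isometry invariance, additivity and refinement stability, forms the
correctness contract of the implementation. Relative track length —
length divided by stature — removes body-size effects; it is computed per
subject and then averaged, not as a ratio of group means (the two differ
whenever heights vary).

**Speed and braking.** Linear speed is the norm of the central-difference
velocity (one-sided at the trial edges). Central differences are exact for
motion affine in time and, at 30 Hz with millimeter-level coordinate
noise, adequate without smoothing; an optional odd-width moving average on
the speed series is exposed (`analysis_options(smooth_window=)`, default
off) for noisier capture. Within each beat, the braking phase runs from
the frame of maximum speed to the *earlier* of the beat's final frame and
the first post-peak frame with speed at or below a zero threshold
(default 1e-3 m/s — effectively "the speed drops to zero" while tolerant
of floating-point dust). The braking metrics are the speed drop
Δv = v_end − v_peak ≤ 0 and mean acceleration ā = Δv/Δt; Δt is measured
peak-to-end, not over the whole beat, which is the only reading that makes
ā a mean over the deceleration interval. A beat whose speed peaks on its
final frame has no deceleration phase; it is flagged degenerate and
excluded from group summaries rather than letting Δt → 0 produce an
unbounded ā. Coordinates are treated as meters throughout; cumulative
per-combination path lengths of 4–8 m are what ~0.9 m arm sweeps over 4–8
beats produce.

## EMG model

RMS over a window, `sqrt(mean(x^2))`, indexes the intensity of motor-unit
recruitment; integrated EMG, the time-integral of the *rectified* signal
(left Riemann sum at 1000 Hz; the trapezoidal option differs negligibly),
indexes total fiber participation. Rectification is required — the
unrectified integral of a zero-mean interference signal is ≈ 0 — and the
same reasoning fixes RMS as the root of the mean *square*.

Standardization divides a task value by the subject's MVIC (maximum
voluntary isometric contraction) reference and is reported in percent.
The reference statistic is the highest-RMS sliding window (default 1 s) of
the MVIC trial — robust to onset/offset — and for iEMG the reference is
the MVIC's mean rectified amplitude times the analysis-window duration, so
iEMG percentages are duration-comparable. Values above 100 % are legal:
dynamic contractions can exceed an isometric maximum. An optional
zero-phase 20–450 Hz Butterworth band-pass (the conventional sEMG
bandwidth) is available before the metrics; it is off by default because
the synthetic carrier is already band-limited.

## The synthetic cohort

The generator produces data with the statistical structure the analysis
assumes, so every stage is testable without recordings.

* **Geometry.** Via-points sit one arm length (0.6 m at the 1.77 m
  reference stature) from the shoulder in the direction each named action
  ends at; the chest cross places each hand 0.15 m across the midline at
  0.55 m forward reach. Per-subject geometry scales with height/1.77, so
  absolute track length varies with stature while relative track length
  removes it — the rationale for the relative index. The chosen
  via-points reproduce the combinations' plane structure: the 8-beat
  sequence travels furthest in the frontal and sagittal planes, the
  4-beat chest-cross sequence in the horizontal plane.
* **Movement model.** Each beat is a straight-line minimum-jerk segment
  `s(τ) = 10τ³ − 15τ⁴ + 6τ⁵` between via-points: smooth, at rest at both
  ends, with a well-defined speed peak (15d/8T) and a terminal
  deceleration phase — exactly what the braking metrics require. The
  group's `braking_sharpness` exponent γ time-warps the profile
  (s(τ^γ)); γ > 1 delays the peak and sharpens terminal braking without
  changing the path (so path length stays exactly linear in the amplitude
  scale). Defaults: A = 1.1, B = 1.0, encoding the stronger braking of
  the skilled group.
* **Amplitude.** Group scales default to A = 1.05, B = 1.00, the ~2–12 %
  (typically ~3–5 %) advantage reported for the skilled group, times a
  per-subject technique factor (`subject_amp_sd = 0.05`, a realistic
  stature-free amplitude CV). Coordinate noise is 3 mm SD, typical of
  video-based digitizing.
* **EMG.** Each channel is `speed envelope × group channel weight ×
  per-trial activation gain × unit-variance 20–450 Hz Gaussian carrier +
  noise`. Group A's weights peak at the latissimus dorsi bilaterally;
  group B's at the left triceps and right biceps; right-side channels are
  multiplied by 1.3 (dominant hand). The activation gain
  (`activation_sd = 0.15`) is the between-trial recruitment variability
  that survives MVIC standardization — without it, standardized EMG and
  track length would correlate at r ≈ 1, unlike any real cohort; with it
  the track-length~EMG correlations come out in the moderate-to-strong
  range.
* **MVIC.** A constant-envelope burst per channel. The envelope level is
  a population constant — 1.4 × the nominal peak task envelope — raised
  per subject if their realized task envelope demands it, so standardized
  task values stay bounded below 100 %. The level is deliberately *not*
  proportional to each channel's task weight: per-channel proportional
  references would cancel the injected dominance pattern on
  standardization (in real data, an MVIC is a muscle property, not a task
  property).
* **Cohort.** 15 athletes by default, split 4/11 (mirroring the
  graded/ungraded split; the true group sizes behind the A/B comparison
  are not public, so they are configuration inputs), heights
  Normal(1.77, 0.09²) m truncated positive, ~90 % right-handed.
  Everything is reproducible from one integer seed; per-subject,
  per-combination, per-stage seeds are derived from it.

**What the generator does not emulate:** no joint kinematics or dynamics
(one marker per hand), no motor-unit action-potential structure or EMG
cross-talk, no fatigue, no camera calibration or reconstruction error
structure, and no group-specific correlation pattern between amplitude
and activation (both groups share one activation-variability model).
Passing tests therefore certify the pipeline's arithmetic and its ability
to recover injected group effects — not the physiological fidelity of any
specific recording system.

## Statistics

Group comparisons use the independent-samples t-test, Student's
pooled-variance variant by default (the classical meaning of the term in
SPSS-era reports; Welch is selectable), two-sided, with significance
flagged at p < 0.05 and p < 0.01. No multiple-testing correction is
applied, matching per-metric reporting practice in this literature.
Correlation grades partition |r| at 0.1/0.3/0.7 into
none/weak/moderate/strong — the conventional bands, configurable because
the source convention is unstated. Minimum group size is 2; a zero-variance
degenerate test is reported non-significant with a warning rather than an
error, and an undefined correlation is surfaced per pair.

## Numerical and design choices

* Beat boundaries are rounded multiples of `(60/tempo) × frame_rate`
  frame offsets; the last boundary is pinned to the trial length, and a
  frame count more than one frame off the expected total is a
  segmentation error, not silently re-partitioned.
* EMG beat windows map boundary times to samples by nearest-sample
  rounding; windows partition the trial exactly, so per-beat iEMG sums to
  the whole-trial iEMG to within accumulation error (tested at 1e-9
  relative).
* CSV numerics are written with 17 significant digits via a fixed format,
  making simulate → analyze → report byte-reproducible under one config;
  the JSON manifests carry no timestamps for the same reason.
* Per-subject error isolation: one unreadable file drops that subject
  from the affected stage only and is logged in the analysis manifest.

## Problem sizes used by the test suite

The oracle suites use 200 random 50-point trajectories; analytic EMG
checks use 10-period sinusoids at 1000 Hz; parameter-recovery checks use
100 seeded cohorts of 15 subjects each for the amplitude effect (A/B
amplitude ratio 1.15 for direction recovery, 1.0 for the null-level check
of the t-test) and 100 seeded cohorts for muscle-dominance and
right-side-dominance recovery under the latissimus-dominant profile.
These sizes give the binomial checks (≥95/100 recoveries; null rejections
within the 95 % band around the nominal 5 %) adequate resolution.

## Known limitations

* The braking endpoint depends on the zero-speed threshold when speed
  hovers near zero; with the default 3 mm coordinate noise at 30 Hz,
  speed noise is ~0.1 m/s, so in practice the endpoint is the beat end.
* Plane projections assume the capture frame is anatomically aligned; no
  re-alignment (e.g., PCA or trunk-based) is performed.
* The t-test layer assumes approximate normality within groups; with
  n = 4 in the smaller group its power is limited, which is faithful to
  the study design it mirrors.
* Real MVIC normalization can exceed 100 % in dynamic tasks; the
  generator's bounded construction intentionally keeps synthetic values
  below 100 %, so >100 % values only arise with user-supplied data.
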