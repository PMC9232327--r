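# armbeat

Biomechanical analysis of metronome-paced ("beat-segmented") arm movements
from 3D motion capture and surface electromyography (sEMG), built around the
protocols used to compare skill groups in competitive Taijiquan arm
manipulation: two fixed lift combinations (an 8-beat and a 4-beat sequence)
performed at 120 beats/min, hand trajectories captured at 30 Hz, and eight
sEMG channels (bilateral biceps brachii, triceps brachii, middle deltoid,
latissimus dorsi) sampled at 1000 Hz.

The package is for movement scientists who want the full chain — amplitude,
braking, muscle activation, group statistics — as tested, reproducible code,
including a seeded synthetic-cohort generator so the whole pipeline runs
without any recorded data.

## What it computes

**Movement amplitude.** The action-track length is the cumulative Euclidean
length of the sampled hand path,

    L = Σ_n sqrt((x_{n+1}−x_n)² + (y_{n+1}−y_n)² + (z_{n+1}−z_n)²),

computed in 3D and projected onto the three anatomical planes (XY =
horizontal, XZ = frontal, YZ = sagittal; x mediolateral, y anteroposterior,
z vertical). The relative track length L/height removes stature effects.
Left and right hands are computed separately, then averaged.

**Braking.** Linear speed is obtained by central finite differences. Within
each beat, braking runs from the frame of peak speed to the earlier of the
beat's end and the first instant speed drops to zero, quantified by the speed
drop Δv = v_end − v_peak (≤ 0; the sign only marks deceleration) and the mean
acceleration ā = Δv / Δt.

**Muscle activity.** Per channel and window (beat or whole trial): RMS
amplitude sqrt(mean(x²)) and integrated EMG ∫|x(t)| dt, standardized as
percentages of a maximum-voluntary-isometric-contraction (MVIC) reference
(the highest-RMS sliding window of the MVIC trial; 100 % anchor).

**Statistics.** Group summaries (mean ± SD, signed A−B differences),
independent-samples t-tests (Student pooled by default, Welch selectable)
with the conventional p < 0.05 / p < 0.01 flags, and a Pearson correlation
panel among track length, RMS % and iEMG % within each group.

**Synthetic cohorts.** Seeded minimum-jerk point-to-point arm motion through
anatomically plausible via-points per beat, with per-group amplitude and
braking-sharpness profiles, plus sEMG whose envelope follows hand speed
scaled by group-specific muscle weights (latissimus-dominant vs
arm-flexor/extensor-dominant, right > left).

## Worked example

```r
library(armbeat)

config  <- cohort_config(seed = 7)            # the default study conditions
script  <- build_combination_script(1)        # 8-beat front/up/side/down lifts
athlete <- subject_profile("S01", "A", height = 1.77)
trial   <- generate_motion_trial(athlete, script, config, seed = 11)

hand_average(
  track_length_summary(trial$left,  athlete$height, "left",  "S01"),
  track_length_summary(trial$right, athlete$height, "right", "S01")
)
#>   subject_id     hand plane length_m relative_length
#> 1        S01 averaged    XY    4.968           2.807
#> 2        S01 averaged    XZ    6.156           3.478
#> 3        S01 averaged    YZ    6.038           3.412
#> 4        S01 averaged   XYZ    7.125           4.025
```

Over the 8-beat combination this athlete's hand travels 7.13 m (4.03 body
heights); the path is longest in the frontal and sagittal planes, as expected
for a front/up/side/down lift sequence. Braking per beat:

```r
braking_average(
  braking_metrics(linear_speed(trial$left),  trial$boundaries),
  braking_metrics(linear_speed(trial$right), trial$boundaries)
)[, c("beat_index", "v_peak", "delta_v", "delta_t", "a_bar")]
#>   beat_index v_peak delta_v delta_t   a_bar
#> 1          1  3.098  -2.957   0.233 -12.674
#> 2          2  3.369  -3.297   0.233 -14.128
#> ...
```

Each 0.5 s beat peaks near 3.4 m/s and sheds essentially all of that speed in
about 0.23 s, a mean deceleration of 12–15 m/s².

The full pipeline runs over directories of CSV files:

```r
simulate_cohort(cohort_config(seed = 7), "cohort/")   # 15 athletes x 2 combos
analyze_cohort("cohort/", "results/")                 # metrics CSVs + report.md
```

or from a shell via the thin wrapper `inst/cli/armbeat.R`
(`simulate`/`analyze`/`report` subcommands with a YAML config).

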