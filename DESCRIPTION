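Package: armbeat
Title: Beat-Segmented Arm Movement Biomechanics from Motion Capture and Surface EMG
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for metronome-paced (beat-segmented) arm movements
    recorded with 3D motion capture and surface electromyography (sEMG).
    Computes cumulative hand-path ("action track") length in 3D and in the
    horizontal, frontal and sagittal anatomical planes, height-normalized
    relative track length, per-beat braking metrics (speed drop and mean
    deceleration from the in-beat speed peak), and MVIC-standardized EMG
    amplitude indices (RMS and integrated EMG) for eight shoulder/arm muscle
    channels. Includes a seeded synthetic-cohort generator (minimum-jerk
    point-to-point arm motion plus band-limited EMG carriers) emulating a
    two-group athlete study, and a statistics layer with independent-samples
    t-tests, group summaries and Pearson correlation panels, plus a
    simulate/analyze/report workflow with CSV interchange.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    signal,
    jsonlite,
    yaml,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
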