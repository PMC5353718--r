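Package: nirsvft
Title: Frontal NIRS Verbal-Fluency Waveform Features and Group Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Simulation and analysis of multi-channel near-infrared
    spectroscopy (NIRS) recordings acquired during a block-design verbal
    fluency task. Provides a synthetic-cohort generator with known ground
    truth (group-dependent hemodynamic response amplitude and latency,
    channel noise, artifact-corrupted channels), extraction of the two
    frontal-region waveform statistics used in clinical NIRS work -- the
    task-period integral and the half-area centroid latency -- with channel
    quality control and baseline correction, covariate-adjusted ANCOVA
    group comparisons with Fisher's LSD post hoc contrasts and Cohen's d,
    Spearman correlations, demographic summary tests, and threshold-based
    individual classification.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    car,
    nortest
Suggests:
    testthat (>= 3.0.0),
    emmeans
Config/testthat/edition: 3
RoxygenNote: 7.3.3
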