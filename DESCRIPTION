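Package: assr40
Title: Source-Level Analysis of 40 Hz Auditory Steady-State Responses and Sustained Fields
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for source-level magnetoencephalography analysis of 40 Hz
    auditory steady-state responses (ASSR) and sustained event-related fields
    (ERF) in developmental cohorts. Provides amplitude-modulated tone stimulus
    synthesis, Morlet-wavelet time-frequency decomposition, inter-trial phase
    consistency (ITPC) with percent-change baseline normalization, z-scored
    sustained-field amplitude extraction, per-subject peak-vertex region-of-
    interest selection, and a hemisphere/age statistical layer (linear
    mixed-effects model with nested amplitude slopes, Pearson age correlations
    with Bonferroni correction). A seeded synthetic cohort generator with
    von Mises trial-phase concentration and 1/f background noise supplies
    ground truth for parameter-recovery and calibration testing; a documented
    plain-text epoch container lets externally preprocessed source time
    courses enter the identical pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    lme4,
    jsonlite,
    data.table
Suggests:
    testthat (>= 3.0.0),
    lmerTest,
    withr
Config/testthat/edition: 3
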