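Package: cardiosleep
Title: Wearable Cardiorespiratory Sleep Staging from Chest-Patch ECG and
    Accelerometry
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: End-to-end pipeline for four-class sleep staging (wake, N1/N2,
    N3, REM) from signals recorded by an adhesive chest patch in the home:
    derivation of a respiratory waveform from three-axis accelerometry by
    windowed principal-axis analysis (with a gravity-plane baseline and an
    orientation-robust variant), a transformer plus dilated-convolution
    sequence-labeling model over whole nights, a leave-one-subject-out
    transfer-learning harness, agreement statistics (accuracy, Cohen's
    kappa), sleep-architecture metrics (TST, TIB, SE, SOL, stage
    percentages), and longitudinal trend summaries for sleep-restriction
    protocols. Includes a statistically structured synthetic cohort
    simulator (stage-dependent heart rate and respiration, posture changes,
    motion artifacts, longitudinal intervention effects) so that every
    stage of the pipeline is exercisable without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    signal,
    jsonlite,
    yaml,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
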