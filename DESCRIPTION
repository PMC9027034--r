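Package: eegscreen
Title: Single-Channel EEG Screening Pipeline for Dementia and Mild
    Cognitive Impairment
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A reproducible analysis pipeline for resting-state,
    single-channel (Fp1) EEG screening of dementia and mild cognitive
    impairment. Generates synthetic cohorts with known class-dependent
    spectral structure and ground-truth artifacts, removes blink and
    movement artifacts by windowed derivative-sum detection followed by
    ensemble empirical mode decomposition with correlation-based
    component rejection, extracts short-time Fourier band and 1-Hz bin
    power features referenced to a control group, screens features with
    Kruskal-Wallis tests under multiplicity correction, and classifies
    subjects with a SMOTE-balanced radial-kernel support vector machine
    under stratified ten-fold cross-validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    signal,
    stats,
    tibble,
    tidyr,
    utils,
    withr
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
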