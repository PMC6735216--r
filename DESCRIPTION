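Package: erdtopo
Title: Event-Related Desynchronization Topography and Channel Selection for
    Motor-Attempt EEG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to quantify event-related desynchronization (ERD) in
    cue-based motor-attempt EEG and to compare channel-selection strategies
    for motor-intent decoding. Provides a synthetic 64-channel EEG generator
    with known ERD ground truth, the standard preprocessing chain (EOG
    removal, average reference, zero-phase FIR band-pass, epoching, baseline
    removal, amplitude-based trial rejection), Morlet-wavelet time-frequency
    analysis, per-channel ERD-ratio topographies, fixed sensorimotor and
    individualized lowest-ERD-ratio channel selection, common spatial pattern
    (CSP) feature extraction with linear support-vector classification under
    stratified cross-validation, and repeated-measures ANOVA with Bonferroni
    post-hoc comparisons of strategy accuracies.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    Rcpp,
    e1071,
    generics,
    ggplot2,
    jsonlite,
    purrr,
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
LinkingTo:
    Rcpp
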