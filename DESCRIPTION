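Package: trailermetrics
Title: EEG and Eye-Gaze Audience-Response Metrics for Movie Trailers
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Computes two neurophysiological audience-response metrics from
    group viewings of video stimuli: attentional asynchrony, the fraction of
    sliding eye-gaze windows whose inter-viewer pairwise distances are
    indistinguishable from a time-misaligned permutation null, and cognitive
    congruency, the largest generalized eigenvalue of cross-viewing
    band-power covariance matrices of EEG recordings.  Includes the EEG
    conditioning chain (resampling, zero-phase high-pass and notch filtering,
    average reference, epoching with baseline removal), complex Morlet
    time-frequency power with band aggregation, stated-preference and
    box-office key-performance-indicator summaries with a leave-one-out
    outlier rule, a regression harness (univariate and bivariate OLS,
    bootstrap standard errors on R-squared, Benjamini-Hochberg correction),
    and synthetic-data generators that plant the structure each metric
    assumes, so the whole pipeline is testable without any recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    signal,
    stats,
    utils,
    yaml
Suggests:
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
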