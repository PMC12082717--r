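Package: preictalr
Title: Personalized Preictal EEG Pattern Characterization
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Retrospective characterization of the preictal interval in
    long-term multi-channel scalp EEG. Recordings are band-pass filtered,
    summarized by ten windowed features (spectral entropy, Hjorth mobility
    and complexity, Higuchi fractal dimension, five relative band powers,
    and the detrended fluctuation exponent), and compared against a
    patient-specific interictal baseline via the Mahalanobis distance.
    Prolonged excursions beyond the interictal 99th percentile define the
    preictal interval; channels are then ranked by logistic-regression F1
    separability and features by coefficient magnitude. Includes EDF
    input/output, a synthetic multi-channel EEG generator with injectable
    preictal anomalies for end-to-end validation, and a batch pipeline.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    glmnet,
    jsonlite,
    Rcpp,
    signal,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
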