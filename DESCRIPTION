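Package: emodyn
Title: Emotion Dynamics and Cognitive Load Analysis from Multichannel EEG
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: A tested pipeline linking EEG emotion dynamics to cognitive load.
    Band-power features are extracted with the Hilbert-Huang transform,
    complexity features with wavelet-packet and entropy estimators
    (approximate, sample, permutation and state-space correlation entropy),
    reduced to a one-dimensional emotion trajectory via correlation-based
    feature selection and Isomap, quantified by a zero-crossing-rate
    statistic, and regressed against the beta/(theta+alpha) engagement
    index of cognitive load. Includes a synthetic-EEG cohort generator with
    known ground truth so every stage is testable without recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    igraph,
    jsonlite,
    signal,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
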