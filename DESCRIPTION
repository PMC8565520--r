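Package: stnerp
Title: EEG Evoked-Response Localization of Subthalamic DBS Electrodes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for localizing deep brain stimulation (DBS)
    electrode contacts from scalp EEG recorded during low-frequency
    stimulation. Covers stimulus-artifact detection and interpolation,
    average re-referencing and zero-phase FIR band-pass filtering, epoching
    and trial-averaged evoked response potentials (ERPs), engineered ERP
    features over predefined time windows, single-feature biomarker
    statistics (independent t-tests, ROC cutoff models with cross-validated
    metrics), and minimum-redundancy maximum-relevance (MRMR) feature
    selection with linear support vector machine classification of
    stimulation site (zona incerta vs. dorso-lateral vs. ventro-medial
    subthalamic nucleus). Ships a synthetic-cohort generator emulating the
    study recordings so the whole analysis runs without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    e1071,
    jsonlite,
    pracma,
    signal,
    stats,
    utils,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0),
    withr
LinkingTo: Rcpp
Config/testthat/edition: 3
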