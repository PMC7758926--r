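Package: pges
Title: Detecting the End of Postictal Generalized EEG Suppression
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Detection of the end of postictal generalized EEG suppression
    (PGES) in multi-channel scalp EEG, framed as classification of 10-second
    bipolar-montage snippets. Provides EEG recording input/output with
    frequency-domain resampling and longitudinal bipolar montaging,
    zero-phase Butterworth bandpass denoising, a 127-dimensional feature set
    built from inter-channel correlations and intra-channel temporal signal
    dynamics, a random-forest snippet classifier, patient-independent
    ROC/AUC evaluation with feature-subset, noise-filter and channel-subset
    ablation experiments, and a synthetic annotated EEG generator so the
    full pipeline runs without protected clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    data.table,
    jsonlite,
    randomForest,
    signal,
    stats,
    utils,
    graphics
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    pROC,
    withr
Config/testthat/edition: 3
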