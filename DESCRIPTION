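Package: fhrfusion
Title: Mixed-Data Neural Classification of Fetal Heart Rate Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: An end-to-end pipeline for dichotomous (healthy versus
    pathological) classification of 2 Hz antepartum fetal heart rate (FHR)
    recordings. Provides signal denoising (gap interpolation, splice
    removal, fixed 20-minute segmentation), the classical computerized-CTG
    feature panel (short-term variability, Delta, interval index, long-term
    irregularity, band powers, approximate entropy, baseline and
    acceleration/deceleration counts), eight signal-to-image encodings
    (scalogram, Gramian angular fields, Markov transition field, recurrence
    matrices, spectrogram, persistence spectrum), a two-branch MLP + CNN
    fusion classifier trained with Adam and early stopping, a repeated
    train/test evaluation protocol with a full confusion-matrix metric
    panel, and a synthetic CTG generator so the whole pipeline is testable
    without clinical data.
License: MIT
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    signal,
    pROC,
    jsonlite,
    yaml,
    EBImage
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse,
    png
Config/testthat/edition: 3
LinkingTo:
    Rcpp,
    RcppArmadillo
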