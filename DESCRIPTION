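Package: neonartefact
Title: Automated Artefact Detection for Single-Channel Neonatal ERP Epochs
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Detects artefact in short (1.5 s) single-channel epochs of
    neonatal stimulus-evoked EEG. Provides zero-phase windowed-sinc FIR
    conditioning, a bank of 31 time-domain, spectral, fractal and wavelet
    features per epoch, consensus labelling from multi-rater panels with
    Cohen's kappa agreement statistics, a certainty-weighted random-forest
    classifier with grouped leave-one-subject-out cross-validation and
    grid search, a full evaluation battery (confusion metrics, ROC/AUC,
    permutation importance, bootstrap subgroup accuracy, evoked-response
    signal-to-noise ratio), and a synthetic-data generator that emulates
    infant ERP epochs, artefact classes and rater panels so that the whole
    pipeline can be exercised without access to clinical recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    ranger,
    signal,
    stats,
    utils
Suggests:
    pROC,
    jsonlite,
    withr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
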