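Package: dysvoice
Title: Acoustic Analysis and Classification of Dysphonic Sustained Vowels
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for voice-based screening of hypokinetic dysarthria from
    sustained-vowel recordings. Provides WAV reading and fixed-length
    segmentation, spectral-gating noise reduction, a suite of clinical
    voice-quality measures (jitter, shimmer, harmonics-to-noise ratio,
    fundamental frequency, formants, spectral descriptors, MFCCs and their
    temporal derivatives), a controllable source-filter synthesizer of
    dysphonic vowels for end-to-end testing, mutual-information and
    recursive-feature-elimination feature selection, convolutional/recurrent
    and classical classifiers, and a cross-validated evaluation suite with
    ROC/AUC and Matthews correlation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    signal,
    e1071,
    xgboost,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse
Config/testthat/edition: 3
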