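Package: depspeech
Title: Depression Screening from Smartphone Read-Speech Recordings
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for detecting major depressive disorder
    from text-dependent read speech (vowel, digit and passage reading tasks)
    recorded on consumer smartphones. Provides spectral-gating noise
    reduction and energy-based voice activity detection, fixed-size log-Mel
    spectrogram segmentation, SpecAugment-style time and frequency masking,
    a compact convolutional neural network trained from scratch on CPU,
    classical MFCC-statistic baselines (linear SVM, LDA, k-nearest
    neighbours, random forest), and a participant-independent
    cross-validated evaluation harness. Includes a seeded source-filter
    synthesizer that generates surrogate read-speech cohorts with a
    configurable class contrast in prosodic and spectral variability, so the
    whole pipeline can be exercised and tested without access to clinical
    recordings.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    utils,
    tools,
    jsonlite,
    yaml,
    e1071,
    MASS,
    class,
    randomForest
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    pROC,
    withr,
    optparse,
    knitr
Config/testthat/edition: 3
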