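Package: semgopt
Title: Feature Optimization and Myoelectric Control Simulation for
    Surface EMG
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Tools for building myoelectric human-computer interfaces
    from multichannel surface electromyography (sEMG). Implements a
    42-dimension per-channel feature bank (time, frequency and
    time-frequency domains), three feature-separability criteria
    (variance-entropy, Euclidean Fisher discrimination, and SVM
    recursive feature elimination) with optimal-feature-number sweeps
    and cross-subject aggregation, channel ranking by single-channel
    classification, a classifier harness (kNN, neural network, random
    forest, support vector machine) with stratified cross-validation,
    zero-phase digital filtering, ICA and multiscale-PCA denoising, a
    seeded synthetic sEMG generator, and a discrete-time simulator of
    window-based telecar control paradigms.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    signal,
    e1071,
    randomForest,
    nnet,
    class,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    kernlab,
    knitr
Config/testthat/edition: 3
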