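Package: museeg
Title: Mobile EEG Analysis of Art Viewing: Preprocessing, Unsupervised
    Clustering and Time-Varying Directed Connectivity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for mobile multichannel EEG recorded
    while subjects freely view visual art. Provides synthetic-session
    generation from time-varying vector-autoregressive ground truth,
    artifact-aware preprocessing (zero-phase high-pass filtering,
    correlation-based bad-channel detection, peripheral-channel removal,
    simplified artifact subspace reconstruction, common average
    referencing, epoch segmentation), stimulus-image complexity features
    and hierarchical class assignment, band-limited time/frequency/wavelet
    EEG features, minimum-redundancy-maximum-relevance feature ranking,
    unsupervised extreme-learning-machine embedding with Gaussian-mixture
    and k-means clustering scored by the Rand index, and Kalman-filtered
    multivariate adaptive autoregressive modelling with the adaptive
    directed transfer function, including pattern-level connectivity
    statistics and group contrasts.
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
    mclust,
    png,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    tiff,
    optparse,
    withr
Config/testthat/edition: 3
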