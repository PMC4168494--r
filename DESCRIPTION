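Package: cbce
Title: Cluster-Based Classifier Ensembles for Smart-Home Activity Recognition
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Trains and applies cluster-based classifier ensembles for
    sensor-based recognition of activities of daily living. Each base
    classifier is a k-means cluster collection built on a random feature
    subset; a support matrix scores how strongly each cluster backs each
    activity class, and predictions fuse per-cluster support with an
    exponential, distance-weighted rule. Includes numeric and binary
    encodings of segmented sensor-event streams, a synthetic smart-home
    event simulator, stratified cross-validation with confusion-matrix
    metrics, the Davies-Bouldin cluster-validity index, and an
    ensemble-size stability experiment, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    optparse,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
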