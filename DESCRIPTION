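Package: semgbench
Title: Benchmarking of Segmentation, Features, and Classifiers for
    Armband sEMG Gesture Recognition
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools to study how signal-processing choices influence
    surface-electromyography (sEMG) gesture recognition with an 8-channel
    armband. Provides a synthetic recording generator that emulates a
    cued alphabet-gesture acquisition protocol, double-threshold energy
    onset detection, sliding-window segmentation with a parameterized
    overlap fraction, a bank of 33 canonical time- and frequency-domain
    sEMG features, literature and data-derived feature sets with a
    rank-based greedy reduction, a nine-classifier cross-validation
    harness with pooled, per-subject, and trial-grouped schemes, and the
    Friedman/Tukey/Nemenyi/Wilcoxon comparison layer with
    critical-distance summaries and confusion-matrix reports.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    MASS,
    class,
    e1071,
    nnet,
    randomForest,
    signal,
    igraph,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse,
    pracma
Config/testthat/edition: 3
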