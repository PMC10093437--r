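Package: ecvalid
Title: Error-Consistency Enhanced Cross-Validation for Classifier Evaluation
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Extends repeated K-fold cross-validation with an error-consistency
    statistic: the Jaccard overlap between the sample-wise error sets produced
    by models trained across validation repetitions. Supports an internal
    approach (one master error set per K-fold repetition) and an external
    approach (per-model error sets on a held-out validation set), sample-size
    down-sampling curves with locally weighted trend lines, bootstrapped
    rolling-window correlations of accuracy and consistency against sample
    size, synthetic dataset generators with controllable error geometry, and
    deterministic mock classifiers that make consistency outcomes exactly
    predictable for testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    e1071,
    randomForest,
    xgboost,
    nnet,
    ggplot2,
    optparse
Config/testthat/edition: 3
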