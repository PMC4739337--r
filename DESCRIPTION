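Package: vimstab
Title: Intrinsic Stability of Random-Forest Variable Importance Measures
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "maintainer@example.org")
Description: Quantifies the self-consistence (intrinsic stability) of
    random-forest variable importance measures across repeated runs, and
    compares it with the traditional stability under data perturbation and
    parameter variation. Provides a bagged CART forest with recoverable
    bootstrap membership and per-node Gini records, mean-decrease-accuracy
    (MDA) and mean-decrease-Gini (MDG) importance, four pairwise stability
    indices (Spearman, Jaccard, Kuncheva, mean absolute relative difference)
    with top-k truncation, repeated-run and cross-validation experiment
    protocols, dataset-indicator correlation analysis, and a synthetic
    classification-data generator emulating both low-dimensional/large-sample
    and gene-expression-like high-dimensional/small-sample regimes.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    randomForest,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
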