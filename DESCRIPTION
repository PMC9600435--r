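Package: mvstack
Title: Multi-View Stacked Generalization for Microbiome Classification
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Multi-view stacked generalization for binary diagnostic
    classification from gut-microbiome abundance profiles and clinical
    metadata. Builds out-of-fold probability meta-features from a
    heterogeneous per-view base-learner suite, fits an elastic-net
    logistic meta-learner on them, and evaluates under class imbalance
    with precision-recall curves, average precision and Matthews
    correlation agreement matrices. Includes ANOVA/FDR feature
    pre-filtering with a Yeo-Johnson power transform, data-space class
    weighting, two-level model interpretation (normalized meta-learner
    weights and permutation feature importance through the full fitted
    pipeline), and a synthetic multi-view cohort generator for
    end-to-end testing without external data.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    ranger,
    xgboost,
    e1071,
    nnet,
    class,
    car,
    jsonlite,
    data.table,
    yaml,
    ggplot2
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
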