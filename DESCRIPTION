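Package: fundusdr
Title: Fundus Image Preprocessing, Class Balancing, and Weighted
    Soft-Voting Ensembles for Diabetic Retinopathy Grading
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: A desk-scale toolkit for five-grade diabetic retinopathy
    classification pipelines. Provides retina photograph preprocessing
    (dark-border trimming, inscribed circular masking, square resizing),
    class-imbalance upsampling by geometric transforms with per-class add
    counts, stratified 3:1:1 dataset splitting, a backbone-agnostic
    classifier contract with a channel-and-spatial attention block and a
    two-phase freeze-then-fine-tune training schedule, F1-weighted
    soft-voting ensembling with a tunable amplification parameter selected
    by a two-stage grid search, and multiclass evaluation (per-class
    precision/recall/specificity/F1, ACA, macro- and micro-F1, one-vs-rest
    AUC). Ships a synthetic fundus-image generator so the whole pipeline is
    testable on one CPU with no external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    EBImage,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    optparse,
    pROC,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
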