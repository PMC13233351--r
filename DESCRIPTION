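Package: cnvrisk
Title: Malignancy Risk Prediction from Host Copy-Number Signal in Microbially
    Admixed Metagenomic Sequencing Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Derives window-level host copy-number-variation (CNV) Z-score
    features from shallow-coverage bronchoalveolar-lavage metagenomic
    sequencing (mNGS) read counts, builds species-level microbial feature
    matrices from Kraken2-style reports, trains and compares malignancy
    classifiers (gradient-boosted trees, random forest, logistic regression),
    and extends training with high-confidence pseudo-labels selected from
    weakly labeled samples. Includes a synthetic cohort simulator with known
    copy-number ground truth so the whole pipeline is testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    dplyr,
    tibble,
    tidyr,
    purrr,
    rlang,
    readr,
    stringr,
    ggplot2,
    generics,
    jsonlite,
    stats,
    utils,
    xgboost,
    randomForest
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    Rsamtools,
    optparse,
    knitr,
    rmarkdown
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
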