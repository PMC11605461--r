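Package: codepaths
Title: Coded EHR Pathways to Diagnosis with Transformer and Count-Based
    Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Derives temporally ordered "pathways to diagnosis" from coded
    primary-care electronic health records, curates raw codes into a
    compact clinical vocabulary, and models the resulting token sequences
    with a small shared-parameter transformer encoder pretrained by masked
    code prediction and fine-tuned with a logistic classification head for
    lung-cancer risk prediction. Includes a nested case-control cohort
    builder, a bag-of-codes logistic-regression comparator, an evaluation
    stack (PPV/sensitivity/AUROC with bootstrap confidence intervals,
    DeLong comparison of correlated AUROCs, threshold sweeps,
    lookback-by-trimming sensitivity grids, subgroup reports), attention
    and cluster based interpretability, and a synthetic coded-EHR
    generator with planted temporal motifs so the whole pipeline is
    exercisable without access to patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    Rcpp,
    stats,
    utils,
    tools,
    glmnet,
    jsonlite,
    cluster
Suggests:
    testthat (>= 3.0.0),
    withr,
    pROC,
    mclust,
    optparse,
    knitr
LinkingTo: Rcpp, RcppArmadillo
Config/testthat/edition: 3
RoxygenNote: 7.3.3
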