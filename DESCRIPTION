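Package: irlncpair
Title: Immune-Related lncRNA-Pair Prognostic Signatures for Radioresistant
    Esophageal Carcinoma
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Screens immune-related long non-coding RNAs (ir-lncRNAs) by
    correlation with immune genes, performs empirical-Bayes moderated
    differential expression with a mean +/- 2 SD fold-change gate, encodes
    relative-expression 0/1 lncRNA pairs, filters pairs by their matching
    rate, and builds LASSO-narrowed multivariate Cox proportional-hazards
    risk models on pair indicators. Provides Kaplan-Meier / log-rank risk
    stratification, time-dependent ROC evaluation of the risk score,
    rank-based comparisons of risk scores across clinical factors,
    hypergeometric over-representation analysis against user-supplied gene
    sets, and 2^-ddCt relative quantification. Includes a synthetic-cohort
    generator emulating a two-group radioresistance discovery cohort and a
    survival validation cohort, plus readers for TSV expression matrices,
    GEO series-matrix files, symbol lists and GMT gene sets.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    limma,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
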