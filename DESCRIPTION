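Package: adiposig
Title: Discovery of Adipose Gene-Expression Signatures Predictive of
    Obesity Predisposition
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools to discover and validate gene-expression signatures of
    obesity predisposition from white adipose tissue transcriptomes.
    Implements phenotype stratification by Ward hierarchical clustering,
    count preprocessing (CPM filtering, TMM normalization, log-CPM),
    per-gene ANOVA differential screening with Benjamini-Hochberg
    correction, PLS-DA with variable-importance-in-projection (VIP)
    marker selection and permutation validation, three-way signature
    intersection with q-value refinement, and multi-study horizontal
    integration (MINT PLS-DA and sparse PLS-DA) with leave-one-study-out
    cross-validation, keepX tuning and ROC/AUC evaluation. A synthetic
    data module generates multi-study mouse- and human-like cohorts with
    planted discriminative genes so the full workflow can be exercised
    and benchmarked at desk scale.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    edgeR,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mixOmics,
    pROC,
    withr
Config/testthat/edition: 3
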