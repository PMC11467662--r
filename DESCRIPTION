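Package: mlgap
Title: Differential-Expression-Aware Classification of Bulk RNA-Seq Counts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: An end-to-end pipeline for two-class classification of bulk
    RNA-Seq count matrices. Implements low-count and near-zero-variance gene
    filtering, median-of-ratios size-factor normalization, a closed-form
    variance-stabilizing transformation, PCA-based gene screening,
    differential-expression feature selection (Welch t with
    Benjamini-Hochberg correction), three modelling arms (plain selected
    genes, autoencoder latent features, MixUp-augmented training data),
    grid-search cross-validated random-forest and gradient-boosting
    classifiers, a three-explainer (SHAP, LIME, variable importance)
    consensus feature selector, and volcano-plot classification of genes.
    A negative-binomial study simulator with planted differentially
    expressed genes makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    ranger,
    xgboost,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr,
    DESeq2
Config/testthat/edition: 3
RoxygenNote: 7.3.3
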