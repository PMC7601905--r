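Package: SASPsurv
Title: Ensemble Ridge-Cox Prognostic Modeling of Senescence-Associated Serum Proteins
Version: 0.99.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Survival analysis pipeline for multiplex serum-protein biomarker
    panels in cervical cancer. Provides quality control and quantification of
    Luminex bead-array data, per-protein quartile proportional-hazards
    screening, an ensemble of L2-penalized Cox risk scores built on repeated
    50/50 train/test splits with percentile-cutoff dichotomization, subsample
    bootstrap and cross-cohort validation, plurality-voting consensus patient
    classification with confidence tiers, and stratified treatment-benefit
    analysis of brachytherapy within senescence-score strata. Includes a
    synthetic-cohort generator with a latent senescence factor so the entire
    pipeline is testable without patient-level data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3.0)
Imports:
    methods,
    stats,
    utils,
    tools,
    survival,
    yaml,
    jsonlite,
    Rcpp,
    S4Vectors,
    SummarizedExperiment
LinkingTo: Rcpp, RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    glmnet,
    withr
Config/testthat/edition: 3
biocViews: Survival, Regression, Classification, QualityControl, Proteomics
RoxygenNote: 7.3.3
Collate: 
    'SASPsurv-package.R'
    'AllClasses.R'
    'AllGenerics.R'
    'RcppExports.R'
    'simulate.R'
    'preprocess.R'
    'survival-engine.R'
    'quartiles.R'
    'ensemble.R'
    'consensus.R'
    'interaction.R'
    'pipeline.R'
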