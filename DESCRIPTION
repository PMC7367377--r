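Package: ssnet
Title: Sample-Specific Network Functional Biomarkers for Tumor Expression Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds per-sample differential-correlation networks from a tumor/normal
    expression cohort and a scored background interaction network, aggregates
    tumor-specific networks into a frequency-based functional network, and screens
    its genes and edges as diagnostic, subtyping and prognostic biomarkers.
    Includes hypergeometric gene-set enrichment, SVM-based tumor/normal
    classification with class-balanced subgroups and cross-validated ROC/AUC,
    consensus clustering subtyping with representative differentially expressed
    genes and subtype-feature association, Kaplan-Meier/log-rank and Cox
    proportional-hazards biomarker screening with LASSO-Cox selection, and a
    synthetic-data generator that emulates the statistical structure the pipeline
    assumes (correlated reference expression over a background network, planted
    edge perturbations, subtype mean shifts, proportional-hazards survival).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    survival,
    glmnet,
    kernlab
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse,
    jsonlite
Config/testthat/edition: 3
RoxygenNote: 7.3.3
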