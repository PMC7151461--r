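Package: voxrad
Title: 3D Radiomics of Subcortical Brain MRI for Neurodegeneration Classification
Version: 0.1.0
Authors@R: person("Maintainer", "voxrad", email = "voxrad@example.org", role = c("aut", "cre"))
Description: Label-based region-of-interest voxel extraction from 3D MRI-like
    volumes, a 107-feature radiomics engine (first-order, 2D/3D shape, and
    gray-level co-occurrence, run-length, size-zone, neighbouring-tone-difference
    and dependence texture families), two-level feature selection (Pearson
    redundancy filter followed by recursive feature elimination), class-weighted
    multiclass classifiers (multi-layer perceptron, gradient-boosted trees,
    random forest, RBF support vector machine) with stratified 5-split
    cross-validation and prediction-confidence reporting, plus a seeded
    synthetic-phantom generator producing labeled subcortical-like cohorts for
    end-to-end validation of the pipeline.
License: MIT
Encoding: UTF-8
Imports:
    glmnet,
    jsonlite,
    stats,
    tools,
    utils
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
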