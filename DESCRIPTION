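Package: PAtriage
Title: Cross-Center Adaptation and Subtype Triage for Primary Aldosteronism
Version: 0.99.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Decides which primary-aldosteronism patients need adrenal venous
    sampling (AVS) from routine clinical and CT markers. Implements a
    variational Bayesian principal component analysis (BPCA) imputer with
    automatic relevance determination that adapts target-center cohorts to a
    data-rich reference center by filling center-specific missing fields;
    binary surgery-track and medication-track classifiers (regularized
    logistic regression, random forest, multilayer perceptron) selected by
    grid search on the harmonic mean of sensitivity and specificity; and a
    sequential triage flowchart (surgery gate on the captopril-challenge
    aldosterone-to-renin ratio, medication gate on CT negativity) with
    cohort-level accounting of the AVS fraction and decision accuracy.
    Includes a synthetic multicenter cohort generator with class-conditional
    marker distributions, CT-visibility structure and per-center missingness
    so the full pipeline is testable without patient data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.3)
Imports:
    methods,
    stats,
    utils,
    S4Vectors,
    SummarizedExperiment,
    glmnet,
    randomForest,
    nnet
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr,
    knitr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'AllGenerics.R'
    'schema.R'
    'standardize.R'
    'bpca.R'
    'classifiers.R'
    'features.R'
    'flowchart.R'
    'io.R'
    'pipeline.R'
    'simulate.R'
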