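Package: StackTox
Title: Stacked-Ensemble Cytotoxicity Screening with Customizable
    Substructure Fingerprints
Version: 0.99.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: An interpretable QSAR screening toolkit for prioritizing
    potentially cytotoxic organic compounds, built around a customizable
    166-key substructure fingerprint engine, an elemental-ratio
    applicability domain for CHONS organics, a curation pipeline that
    converts IC50 measurements (nM) into binary toxicity labels at the
    log10 = 4 threshold, a stacking ensemble of six base classifiers with
    a logistic meta-model tuned by a biobjective strategy, binary-entropy
    prediction confidence tiers, and Shapley-value attribution that maps
    fingerprint bits back to toxicity-driving substructures. A synthetic
    compound generator with planted substructure-toxicity relationships
    makes every stage testable without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    tools,
    graphics,
    glmnet,
    ChemmineOB,
    e1071,
    ranger,
    xgboost,
    rpart,
    class,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    pROC,
    optparse
biocViews: Cheminformatics, Classification, FeatureExtraction, Software
Config/testthat/edition: 3
RoxygenNote: 7.3.3
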