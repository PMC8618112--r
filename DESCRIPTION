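Package: aquatox
Title: Random-Forest QSAR Models for Acute and Chronic Aquatic Toxicity
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Builds quantitative structure-activity relationship (QSAR)
    regression models for acute (EC50/LC50) and chronic (NOEC) aquatic
    toxicity endpoints across three trophic levels (alga, daphnid, fish).
    Covers curation of replicate toxicity records (qualifier filtering,
    salt stripping and neutralization, mg/L to mmol/L conversion,
    factor-of-10 replicate consistency, water-solubility screening,
    Box-Cox response normalization with +/- 3 SD outlier removal, and a
    pH-microspecies screen for algal data), open 2D molecular descriptor
    computation with constant and correlation pruning, genetic-algorithm
    and random-forest (VSURF-style) variable selection, rational 80:20
    training/validation splitting by PCA-and-response dissimilarity,
    bootstrap-tuned random-forest regression, and a dual applicability
    domain combining k-nearest-neighbour distance thresholds with a
    six-metric prediction-error model selected over a 32-combination
    grid.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.2)
Imports:
    methods,
    stats,
    utils,
    randomForest,
    rpart,
    MASS,
    jsonlite,
    yaml,
    ChemmineR,
    ChemmineOB
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
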