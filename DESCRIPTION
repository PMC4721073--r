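Package: genecol
Title: Genecology Analysis of Common-Garden Provenance Trials
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for genecology studies of forest tree provenance trials in
    controlled common-garden environments. Computes the electrolyte-leakage
    index of freeze injury, decomposes phenotypic variance into nested random
    effects by REML with standard errors propagated to the among-population
    differentiation statistic V_pop (a proxy for Q_ST), builds normalized and
    imputed population-by-trait matrices, partitions populations into groups of
    similar multitrait adaptation with a multivariate regression tree on climate
    or ecosystem predictors, and assembles seed-zone reports. Includes a
    synthetic-data generator that emulates an incomplete-block growth-chamber
    provenance trial with known ground truth, so every analysis stage is
    testable without field data.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    Matrix,
    mclust,
    emmeans,
    jsonlite,
    MASS,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
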