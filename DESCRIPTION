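Package: flockBLUP
Title: Pedigree-Based Genetic Evaluation and Flock Management for Sheep
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Genetic evaluation toolkit for pedigreed sheep flocks driven by
    flat-file records. Builds numerator relationship matrices and their sparse
    inverses, computes inbreeding coefficients by the recursive tabular method
    and by Wright's path-counting rule, estimates heritability by nested-ANOVA
    sib analysis and by EM-REML under an animal or sire model, solves
    Henderson's mixed-model equations for BLUP breeding values, constructs
    economically weighted selection indices, trains a small feed-forward
    network that predicts breeding values from phenotypes, and derives
    date-indexed farm reports (inventories, lambing, production, wool, health,
    disposal, trends) from event-sourced CSV records. A seeded flock simulator
    with known genetic parameters provides ground truth for every method.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    lme4,
    withr
Config/testthat/edition: 3
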