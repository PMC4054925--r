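Package: gepqsar
Title: QSAR Modelling by Heuristic Descriptor Selection and Gene
    Expression Programming
Version: 0.1.0
Authors@R: person("Package", "Author", email = "maintainer@example.org",
    role = c("aut", "cre"))
Description: Tools for building quantitative structure-activity
    relationship (QSAR) models of enzyme inhibition from molecular
    descriptor tables.  Implements the CODESSA-style heuristic method
    (rule-based descriptor pre-filtering, pairwise collinearity control,
    and a heuristic best-subset multiple linear regression with
    leave-one-out cross-validation), and a gene expression programming
    (GEP) symbolic-regression engine with multigenic Karva-notation
    chromosomes carrying random numerical constants.  Includes a
    synthetic benchmark generator emulating a matrix-metalloproteinase
    (gelatinase) inhibition study with 33 pyrrolidine derivatives, and
    evaluators for that study's published linear and GEP models.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
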