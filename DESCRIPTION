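Package: healthspace
Title: Deep Ordinal Neural Network Health Space Models
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Maps an individual's clinical covariates to a two-dimensional
    Health Space with biologically named axes (oxidative stress, metabolic
    stress). Each axis score is the shared linear predictor of a cumulative
    logit model fitted on axis-specific covariates: either a deep ordinal
    neural network (DONN) with consistent rank logits, one of four binary
    deep neural network variants obtained by collapsing the ordinal outcome,
    or the classical proportional odds model. Includes the Health Space
    Index (pairwise confidence-ellipse Jaccard separation), clustering
    validity indices, bootstrap model comparison, a synthetic cohort
    generator with a known cumulative-logit generating process, and a
    command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    MASS,
    jsonlite,
    stats,
    graphics,
    grDevices,
    utils
Suggests:
    testthat (>= 3.0.0),
    cluster
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
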