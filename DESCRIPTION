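Package: phylotaste
Title: Phylogenetic Mixed Models Linking Chemosensory Panel Data to Therapeutic Use
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing tasting-panel assessments of botanical drugs
    together with binary therapeutic-use records on a phylogeny. Provides
    readers and validators for panel datasets, per-trial chemosensory
    intensity and complexity and per-drug therapeutic versatility, grafting of
    missing taxa onto an ultrametric supertree and construction of the
    phylogenetic correlation matrix, a from-scratch Bayesian MCMC engine for
    generalised linear mixed models with covariance-structured random effects
    (gaussian, binary-probit and zero-truncated Poisson families,
    parameter-expanded variance priors, posterior sign-crossing significance
    p_x and phylogenetic heritability h^2), an orchestrated battery of
    versatility and per-use models with magnitude-of-effect aggregation, and a
    synthetic-data generator with known ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ape,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
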