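Package: pojsdm
Title: Presence-Only Joint Species Distribution Models with Shared CAR
    Spatial Effects and Taxonomic Background Samples
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Bayesian joint species distribution modelling for
    presence-only occurrence data on areal lattices. Each taxon of
    interest has a logistic ecological-suitability process and all taxa
    share a logistic sampling-effort process; the two are combined per
    taxon by a convex mixture and both are anchored by a single proper
    conditional autoregressive (CAR) spatial random field. The
    sampling-effort process is identified through a complementary
    sample derived from the taxonomic tree: presences of taxa that lie
    under the lowest common ancestor of the taxa of interest but
    outside their own subtrees act as informed background data and
    pseudo-absences. The package provides lattice construction and
    point aggregation, taxonomic-tree utilities (lowest common
    ancestor, complementary taxa, complementary response), a generative
    simulator, MCMC posterior inference with missing-cell augmentation,
    convergence diagnostics, posterior maps of the latent processes and
    k-fold cross-validated ROC/AUC.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Matrix,
    Rcpp,
    jsonlite,
    methods,
    mgcv,
    stats,
    utils
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    rjags,
    pROC,
    ape,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
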