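Package: cgfunnel
Title: Multi-Level Bayesian Optimization over Hierarchically Coarse-Grained
    Chemical Spaces
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Funnel-like molecular discovery across coarse-grained (CG)
    chemical spaces of increasing bead-type resolution. Builds the three-level
    Martini-style bead-type hierarchy (15, 45 and 96 types), enumerates and
    counts all connected CG molecules of up to four beads by isomorphism-free
    colored-graph generation, embeds each space into a five-dimensional latent
    space with a permutation-invariant graph autoencoder, and runs
    Gaussian-process Bayesian optimization with expected improvement in which
    the prior mean at each resolution is the mapped posterior of the
    next-lower resolution (delta learning). Includes a seeded synthetic
    free-energy oracle with additive-plus-pairwise energetics and hierarchical
    child-averaging, resolution-switching policies, weighted k-medoid
    initialization, and post-hoc analyses (chemical neighborhood sizes,
    density projection across levels, LASSO design-rule extraction).
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    glmnet,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    igraph,
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
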