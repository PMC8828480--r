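Package: velofate
Title: Velocity-Directed Markov Chain Fate Mapping for Single-Cell Data
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Directed single-cell fate mapping from an expression matrix and a
    matching velocity field. Builds a symmetrized k-nearest-neighbour graph on
    the phenotypic manifold, directs its edges by correlating velocity vectors
    with local state-change vectors (with deterministic, analytic-uncertainty
    and Monte-Carlo modes), coarse-grains the resulting Markov chain into soft
    macrostates by Generalized Perron Cluster Cluster Analysis (GPCCA) on a
    sorted real Schur basis, classifies macrostates as initial, terminal or
    intermediate from stability indices and the coarse-grained stationary
    distribution, computes per-cell fate probabilities by sparse absorption
    solves, and derives circular fate embeddings, lineage-priming scores,
    putative driver genes and fate-weighted gene-expression trends along
    pseudotime. Includes seeded generators for planted-macrostate chains,
    branching vector fields and trend families with known ground truth.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Matrix,
    igraph,
    splines,
    jsonlite,
    yaml,
    Rcpp
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    mgcv
Config/testthat/edition: 3
RoxygenNote: 7.3.3
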