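Package: spotacc
Title: Community Connectivity Analysis for Spatial Transcriptomics
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Analysis of community connectivity for high-throughput spatial
    transcriptomics. Builds spot-spot nearest-neighbor similarity networks
    from gene expression (highly variable genes, PCA embedding) and spatial
    coordinates, integrates them into a multi-layer binary graph, and fits a
    Bayesian multi-layer stochastic block model by Gibbs sampling with
    conjugate Dirichlet and Beta priors. Label switching is handled by a
    canonical first-occurrence relabeling applied at every iteration, and
    community labels are estimated by the maximum a posteriori sample.
    Within- and between-community connectivity are summarized with
    equal-tailed credible intervals, either from posterior samples or
    analytically from externally supplied cluster labels. A lattice-based
    simulator generates banded tissue layouts with known connectivity for
    validating label and parameter recovery.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    igraph,
    jsonlite,
    Matrix,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    mclust,
    optparse,
    testthat (>= 3.0.0),
    yaml
Config/testthat/edition: 3
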