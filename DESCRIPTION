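Package: mmdma
Title: Unsupervised Manifold Alignment of Single-Cell Multi-Omics Data
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Joint embedding of single-cell data sets measured by different
    omics assays (an in silico co-assay) when no cell-level or feature-level
    correspondence is available. Each domain enters as a kernel Gram matrix;
    kernel-expansion coefficient matrices are optimized by Adam gradient
    descent with random restarts so that the latent point clouds match in
    distribution (a maximum mean discrepancy term) while preserving
    within-domain structure (a distortion term) and avoiding degenerate maps
    (an orthogonality penalty). Includes synthetic benchmark generators
    (branching manifold, Swiss roll, circular frustum) and the "fraction of
    samples closer than the true match" (FOSCTTM) alignment metric.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    jsonlite,
    Rcpp,
    stats,
    utils,
    graphics,
    grDevices
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr,
    yaml
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
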