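Package: schic3d
Title: 3D Chromosome Structure Inference from Single-Cell Hi-C Contact
    Matrices
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Estimates three-dimensional chromosome conformations from
    sparse single-cell Hi-C contact matrices by penalized maximum a
    posteriori curve fitting. Contact counts are modelled as Poisson draws
    whose means follow a power law in the pairwise spatial distance;
    the negative log-likelihood is regularized by a uniform-spacing
    penalty, a smoothness (bend-angle) penalty, and an optional bulk
    Hi-C population prior that is absorbed algebraically into the data.
    Optimization proceeds coarse-to-fine over a series of merged-bin
    contact matrices with quasi-Newton descent and analytic gradients.
    Includes a simulator for ground-truth curve ensembles and
    Poisson-sampled contact matrices, Procrustes alignment and RMSD
    tools for comparing solution ensembles in shape space, hierarchical
    clustering of solutions, and scripted simulation experiments.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    graphics,
    grDevices,
    Rcpp,
    vegan,
    jsonlite,
    withr,
    bio3d
LinkingTo:
    Rcpp,
    RcppArmadillo
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
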