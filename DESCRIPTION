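Package: hdpseg
Title: Joint Bayesian Segmentation of Grayscale Images with
    MRF-Regularized Dirichlet Processes
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Nonparametric Bayesian segmentation of one or many 2-D
    grayscale images (e.g. lung CT slices). Each image is modelled as a
    Dirichlet process mixture of Gaussian intensity classes regularized
    by a Potts-type Markov random field; multiple images are segmented
    jointly under a hierarchical Dirichlet process so that intensity
    classes (organs, tissues) are shared across images while each image
    uses its own subset. Inference is collapsed Gibbs sampling in the
    Chinese restaurant franchise representation, with mode-based label
    extraction, a brute-force posterior oracle for tiny instances,
    a synthetic CT-like phantom generator with ground truth, and
    Jaccard-index evaluation with optimal label matching.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    png,
    tiff,
    jsonlite
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    RNifti,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
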