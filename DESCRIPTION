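Package: ranmvpa
Title: Multivariate Pattern Analysis of Rapid Automatized Naming fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Longitudinal multivariate pattern analysis of block-design
    rapid automatized naming (RAN) fMRI. Computes voxel-wise temporal-average
    Letter > Color BOLD contrasts, maps them onto an atlas parcellation,
    selects regions by a two-class Fisher criterion swept over a threshold
    grid, classifies groups with a linear support vector machine under
    leave-one-out cross-validation with Monte Carlo permutation inference,
    projects SVM weight vectors back into voxel space with cluster-extent
    thresholding, and stratifies patients into high and low performers on
    standardized reading scores. Includes a synthetic cohort generator that
    emulates a nested three-visit two-group design with a lateralized planted
    effect and score-linked regional signal, so the full pipeline is testable
    without access to clinical data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    RNifti,
    igraph,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    e1071,
    jsonlite,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
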