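Package: banditrsa
Title: Cross-Term Reinforcement Learning and Representational Similarity
    Inference for Correlated Bandit Tasks
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates correlated one-armed-bandit tasks in which two of three
    stimuli share a latent outcome-probability process, fits a cross-term
    delta-rule learner (and its nested structure-naive variant) to choice data
    by bound-constrained maximum likelihood, and compares the models by
    cross-validated likelihood, cross-term hypothesis tests and information
    criteria. Provides the model-based fMRI stack needed to test whether
    neural patterns generalize over relational structure: double-gamma HRF
    convolution and event-based GLM design matrices, multivariate noise
    normalization (prewhitening), cross-run correlation-distance
    representational dissimilarity matrices with a meaningful diagonal,
    volumetric k-nearest-voxel searchlights, sign-flip permutation tests with
    max-cluster-mass family-wise error correction, ROI-averaged tests,
    leave-one-out robustness checks and dendrograms. A synthetic multi-subject
    BOLD phantom with planted representational geometry makes the whole
    pipeline testable end to end without any imaging data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    dplyr,
    ggplot2,
    igraph,
    jsonlite,
    lhs,
    purrr,
    Rcpp,
    rlang,
    RNifti,
    stats,
    tibble,
    tidyr,
    utils,
    withr
LinkingTo:
    Rcpp
Suggests:
    readr,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
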