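Package: cbfc
Title: Cerebro-Cerebellar Resting-State Functional Connectivity Analysis
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Seed-based resting-state functional connectivity analysis of
    cerebro-cerebellar networks. Builds cortical network seeds from a
    17-network parcellation (nearest-neighbour label resampling, limbic
    merge, minimal-representation exclusion, one-layer erosion), conditions
    BOLD series (volume discard, Gaussian spatial smoothing, Gaussian
    running-mean band-pass, Jenkinson motion QC), fits voxelwise first-level
    GLMs with white-matter/CSF/motion nuisance regressors, performs
    group contrasts with covariates and Freedman-Lane permutation
    cluster-extent inference, scores overlap of thresholded group maps
    against a canonical cerebellar parcellation (accuracy, sensitivity,
    specificity, winner-take-all maps), and correlates cluster connectivity
    with symptom scales under Bonferroni control. A synthetic-cohort
    generator with known network coupling provides ground truth for every
    stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    RNifti,
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
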