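Package: rehoband
Title: Frequency-Resolved Regional Homogeneity Analysis of Resting and Task fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for frequency-resolved regional homogeneity (ReHo) analysis
    of BOLD fMRI across resting and task states. Implements temporal
    preprocessing (volume trimming, motion quality control, nuisance
    regression, ideal band-pass filtering into the canonical slow-2 to slow-6
    bands), voxel-wise Kendall's coefficient of concordance maps with
    subject-wise z-standardization and Gaussian smoothing, voxel-wise
    group-by-state interaction mapping with Monte-Carlo cluster-extent
    correction and post-hoc t-tests, seed-based functional connectivity with
    Fisher z transformation, and scoring of delayed match-to-sample behavioral
    logs with bootstrap brain-behavior correlation. A synthetic phantom module
    generates two-group, two-state cohorts with band-limited locally
    synchronized signal planted in known clusters so the whole pipeline is
    testable without real data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    RNifti,
    jsonlite,
    Rcpp,
    stats,
    utils,
    tools
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    optparse,
    yaml
Config/testthat/edition: 3
RoxygenNote: 7.3.3
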