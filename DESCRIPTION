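Package: penumbra
Title: White-Matter Hyperintensity Penumbra Analysis with
    Susceptibility-Separation Metrics
Version: 0.1.0
Authors@R: person("Package", "Maintainer", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Analysis pipeline for myelin-sensitive (chi-negative) and
    comparison white-matter metrics in lesioned brains: lesion mask geometry
    (normal-appearing white matter derivation, distance-binned penumbra rings,
    voxelwise lesion frequency maps), spatially matched covariate-adjusted
    difference scores against a control-group reference atlas, penumbra
    gradient inference with one-sample tests and Cohen's d, pairwise
    correlations, ridge regression with effective-degrees-of-freedom t-based
    inference and partial R-squared effect sizes, voxelwise FDR group mapping
    with cluster extent thresholding, a Trail-Making-Test processing-speed
    compound, and a seeded synthetic cohort generator that plants lesion
    effects with a boundary-distance decay so the whole pipeline is testable
    without patient data. Includes minimal NIfTI-1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
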