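Package: ironmap
Title: Permutation-Based Localization and Statistics of Thalamic Iron
    Accumulation in Phase-Filtered SWI
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Voxel-wise permutation testing with threshold-free cluster
    enhancement (TFCE) to segment regions of elevated phase-filtered
    susceptibility-weighted MRI (SWI) intensity - a proxy for tissue iron -
    inside a thalamus mask, followed by a region-level statistical suite
    (group summaries, Cohen's D for unequal variances, Welch t-test,
    effect-coded multivariate regression and sequential ANCOVA with a
    Group-by-Age interaction) on per-subject average intensities.  Includes
    a calibrated synthetic-cohort generator producing NIfTI volumes with
    planted iron-accumulation clusters, so the full pipeline is testable
    without clinical data, plus minimal NIfTI-1 input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    Rcpp,
    stats,
    graphics,
    utils,
    tools
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0), jsonlite, optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
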