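Package: natisc
Title: Intersubject Correlation Analysis for Naturalistic fMRI
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for analysing stimulus tracking in naturalistic fMRI with
    leave-one-out intersubject correlations (ISC). Covers subject-specific
    functional ROI definition from localizer contrast maps (top-percentile
    voxel selection within group parcels), region-level time-course
    preprocessing and ISC computation with the Fisher transform, peak- and
    trough-removal analyses with a random time-point-removal permutation
    null, a crossed-random-intercept mixed-model suite for condition-type
    contrasts, and Content-Unit scoring of free-text stimulus descriptions
    as a semantic-richness covariate. Includes a synthetic-data generator
    with an additive shared-signal model whose expected ISC is available in
    closed form, used throughout for calibration and testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    RNifti
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
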