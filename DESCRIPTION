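Package: fundusMA
Title: Microaneurysm Detection and Screening Statistics for Retinal Fundus
    Images
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Detects microaneurysms, the earliest visible lesion of diabetic
    retinopathy, in colour digital fundus photographs. Implements a
    three-stage pipeline: shade-corrected red-free preprocessing with a
    field-of-view and quality gate, multilayered dark-object candidate
    extraction tuned to lesions approximately seven pixels in diameter at a
    canonical scale, and confirmation of candidates by the rotational
    symmetry of singular-spectrum-analysis smoothed cross-sectional
    intensity profiles. Ships a synthetic fundus-image generator with ground
    truth for end-to-end evaluation, and screening statistics
    (sensitivity, specificity, cross-cohort dispersion, and
    prevalence-standardized predictive values).
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Rcpp,
    jsonlite,
    yaml,
    png,
    stats,
    tools,
    utils
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    tiff,
    jpeg,
    optparse
Config/testthat/edition: 3
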