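Package: metconn
Title: Single-Subject Metabolic Brain Network Analysis from Longitudinal FDG-PET
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Builds single-subject ("individual") metabolic covariance brain
    networks from longitudinal FDG-PET. Quantifies regional standardized
    uptake value ratios (SUVR) against a pons reference over a 120-region
    parcellation (AAL-116 plus pons, dentate nuclei and red nucleus),
    constructs stage-pair connectivity matrices from the effect-size
    difference of standardized SUVR changes via a Fisher-type transform,
    binarizes them over a 101-point threshold sweep, summarises metabolic
    dynamics of six functional subnetworks with one-way ANOVA and Tukey
    post-hoc contrasts, and performs seed-based dentato-rubro-thalamo-cortical
    pathway accounting. Includes a seeded synthetic-data generator with edge
    ground truth for validation, a clinical symptom-grading timeline, and
    BrainNet Viewer export.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    RNifti,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
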