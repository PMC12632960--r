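Package: molbrainage
Title: Molecular-Enriched Brain-Age Modeling from Functional and Structural MRI Features
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.com", role = c("aut", "cre"))
Description: A tested pipeline for molecular-enriched brain-age analysis:
    two-stage dual-regression (REACT) of BOLD time series against
    neurotransmitter-transporter density templates, atlas parcellation of the
    resulting enriched connectivity maps into regional feature blocks,
    location/scale (ComBat) harmonization of multi-site feature tables with an
    optional subgroup-wise empirical-Bayes variant, and brain-age prediction
    with support vector regression under repeated age-stratified nested
    cross-validation, including bias metrics. Ships a synthetic-data module
    that generates BOLD runs with planted template-weighted signal, multi-site
    cohorts with known age, sex, and site effects, structural morphometry
    fixtures, and image-quality tables with planted outliers, so every stage
    is testable against known ground truth.
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
    utils,
    withr,
    e1071,
    RNifti
Suggests:
    MASS,
    sva,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
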