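Package: connfroi
Title: Predicting Category-Selective Visual Regions from Resting-State
    Functional Connectivity
Version: 0.1.0
Authors@R:
    person("Fiona", "Mercer", email = "fmercer@example.org",
           role = c("aut", "cre"))
Description: Predicts individual-specific category-selective visual regions
    (functional regions of interest, fROIs) from resting-state functional
    connectivity fingerprints. Builds vertex-to-parcel Fisher-z connectomes,
    fits l2-regularized linear models with nested leave-one-subject-out
    cross-validation to predict task contrast maps, extracts fROIs by
    top-fraction thresholding of predicted maps, and evaluates category
    selectivity (percent signal change, paired t-tests, mixed-design ANOVA
    with subject as a random factor) against localizer-defined and
    atlas-defined regions. Ships a synthetic-cohort generator with a known
    linear coupling between connectivity and task activation so the whole
    pipeline can be validated end-to-end with ground truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    data.table,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
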