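Package: tauextent
Title: Spatial Extent Analysis of Regional Tau-PET Abnormality
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Data-driven regional abnormality thresholds for tau-PET SUVR via
    two-component Gaussian mixture modelling, a whole-brain spatial extent
    index (count of abnormal regions among 70 Desikan-based regions),
    cross-sectional and longitudinal Braak-staging conformance, regional
    progression classification between scans, between-subject pattern
    heterogeneity via Jaccard similarity, and head-to-head comparison of tau
    metrics as predictors of cognitive performance and decline (linear models
    with Vuong's closeness test and FDR control). Includes a synthetic-cohort
    generator with exposed ground truth for validation, and an end-to-end
    pipeline driver.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    lme4,
    jsonlite,
    yaml,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    mclust,
    withr
Config/testthat/edition: 3
RoxygenNote: 7.3.3
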