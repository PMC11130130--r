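Package: maizegap
Title: Yield-Gap Analysis of Smallholder Maize Surveys in Sub-Saharan Africa
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: A tested pipeline for analysing field-level maize survey data from
    smallholder systems: quality control with auditable removal reports,
    agro-climatic zonation (growing-degree days, aridity index, temperature
    seasonality), per-zone conditional inference trees to identify
    yield-improving management practices, technology-level comparison with a
    square-root-scale linear mixed model and back-transformed marginal means,
    self-sufficiency scenario projection to 2050, and extrapolation safeguards
    (spatially matched cross-validation folds and an environmental
    dissimilarity index). A synthetic survey generator with known effect
    structure makes every stage testable offline and parameter recovery
    measurable.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    geosphere,
    jsonlite,
    lme4,
    stats,
    utils,
    xgboost,
    yaml
Suggests:
    emmeans,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
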