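Package: opioidits
Title: Opioid Misuse Indicators and Segmented Interrupted Time-Series
    Analysis for Outpatient Claims
Version: 0.1.0
Authors@R:
    person("Package", "Author", , "maintainer@example.org", role = c("aut", "cre"))
Description: Derives monthly opioid-misuse indicators from outpatient
    pharmacy claims tables: the proportion of patients on high-dose opioid
    treatment (100 morphine milligram equivalents per day or more), the
    proportion receiving opioids from multiple providers, the prescription
    overlap rate per patient, and the naloxone use rate among opioid
    users.  Fits segmented regression models with up to two interruptions
    to the resulting monthly series, choosing between ordinary least
    squares and exact stationary AR(1) maximum likelihood according to a
    Durbin-Watson test of the residuals, and reports level and trend
    changes with counterfactual predictions.  Includes a synthetic claims
    generator whose monthly indicator prevalences follow a configurable
    segmented linear model, so the whole pipeline can be exercised and
    validated without access to restricted national claims data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    ggplot2,
    jsonlite,
    rlang,
    stats,
    utils,
    yaml
Suggests:
    lmtest,
    nlme,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
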