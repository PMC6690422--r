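Package: densrisk
Title: Mammographic Density in Case-Control Breast Cancer Risk Models
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org",
    role = c("aut", "cre"))
Description: Tools for adding mammographic density (clinical BI-RADS
    category or automated volumetric percent density) to a
    questionnaire-based absolute breast cancer risk assessment in a
    case-control design. Implements residualization of density on age and
    body mass index via additive spline models fitted to controls,
    adjusted logistic regression with interquartile odds ratios and
    likelihood-ratio tests, matched concordance, weighted-kappa agreement
    between density gradings, combination of the density relative risk
    with a 10-year absolute risk, and a synthetic case-control generator
    that emulates the joint structure of density, age, BMI, demographic
    covariates and baseline risk for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    splines,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    mgcv
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
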