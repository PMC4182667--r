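Package: riskconcord
Title: Individual-Level Agreement of 10-Year Cardiovascular Risk Predictions
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for evaluating how well Cox-form 10-year cardiovascular risk
    scores (the Framingham/ASSIGN/QRISK2 family) predict risk for individual
    people rather than on average. Provides a coefficient-file-driven risk-score
    engine, cause-specific proportional-hazards models with fractional-polynomial
    covariate transforms and product-integral cumulative-incidence prediction
    under competing risk of non-cardiovascular death, chained-equation multiple
    imputation with Rubin's-rules pooling, a synthetic primary-care cohort
    generator with known ground-truth hazards, and agreement analytics:
    intraclass correlation, risk-difference band tables, vigintile calibration
    against Aalen-Johansen observed risks, threshold-consistency and
    case-capture tables, and secular-trend and informative-missingness bias
    checks.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    survival,
    nnet,
    jsonlite,
    stats,
    utils,
    tools
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
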