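Package: comorbidcost
Title: Incremental Comorbidity Burden in Psoriasis Claims Cohorts
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for estimating the incremental healthcare-utilization and
    cost burden of comorbidities in psoriasis cohorts built from
    administrative claims. Includes a seeded synthetic claims generator with
    the statistical structure the analysis assumes, an inclusion/exclusion
    cohort builder with treatment-based severity classification, comorbidity
    flagging and Charlson scoring, bivariate descriptive comparisons,
    Poisson incidence-rate-ratio models for utilization, two-part
    (logistic + gamma) semicontinuous cost models with recycled-prediction
    (marginal standardization) incremental cost estimates and percentile
    bootstrap confidence intervals, and human-capital valuation of
    short-term-disability days.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    data.table (>= 1.14),
    stats,
    utils,
    tools,
    yaml,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
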