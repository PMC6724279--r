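Package: pumpcea
Title: Cost-Effectiveness Microsimulation of Insulin Pump Therapy in Type 1 Diabetes
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Patient-level health-economic evaluation of continuous
    subcutaneous insulin infusion (CSII) versus multiple daily injections
    (MDI) in adult type 1 diabetes, built around the cohort treated at the
    Mexican Institute of Social Security (IMSS).  Provides a synthetic
    cohort generator matched to the published baseline table, an
    annual-cycle Monte Carlo microsimulation of diabetes complications with
    HbA1c-dependent risk adjustment, costing in 2016 Mexican pesos with a
    human-capital indirect-cost option, utility weighting with the
    lowest-utility combination rule, discounting, ICER and net-monetary-
    benefit calculation, cost-effectiveness acceptability curves, and a
    declarative scenario/sensitivity-analysis runner.
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
    purrr,
    rlang,
    stats,
    tibble,
    tidyr,
    truncnorm,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
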