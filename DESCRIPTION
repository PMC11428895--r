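Package: pigspread
Title: Counterfactual Wild Pig Spread Forecasting and Safeguarded-Resource Valuation
Version: 0.1.0
Authors@R:
    person("Pigspread", "Maintainers", email = "maintainers@pigspread.org",
           role = c("aut", "cre"))
Description: Forecasts the county- and watershed-scale spread of invasive wild
    pigs (Sus scrofa) under a no-intervention counterfactual using two
    frameworks: least-squares boosted regression trees with deterministic
    step-ahead forecasting of annual occupancy change, and a stochastic dynamic
    occupancy simulation with beta-distributed annual invasion and extinction
    counts and probability-weighted invasion assignment. Converts forecast
    occupancy into safeguarded agricultural resource quantities (acres, head)
    and dollar values from prices, state yields, and pasture cash rents. A
    synthetic-landscape generator emulates the national county/watershed data
    structure so the whole pipeline runs at desk scale with known truth.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    lme4,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
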