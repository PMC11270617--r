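Package: physflow
Title: Stock-Flow-Consistent Forecasting of Physician Supply
Version: 0.1.0
Authors@R:
    person("physflow", "maintainers", email = "physflow@example.org",
           role = c("aut", "cre"))
Description: A population-dynamic, stock-flow-consistent model of the
    physician workforce. Estimates age- and sex-specific effective exit
    rates from age-grouped annual head-count panels, calibrates workforce
    entry parameters (entry probability and field-choice probabilities)
    against historical stocks by chi-squared grid search or projected
    gradient descent, forecasts supply per medical field to a chosen
    horizon, and computes density gaps against constant-density
    requirement curves under demographic scenarios and a COVID-19
    outpatient-demand shock. Includes a synthetic-data generator with
    known ground truth so the full pipeline is testable without any
    external data download, plus a command-line interface.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    stats,
    utils,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    withr,
    optparse
Config/testthat/edition: 3
RoxygenNote: 7.3.3
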