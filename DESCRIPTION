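Package: inactcost
Title: Opportunity-Cost Modelling of Reducing Population Physical Inactivity
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Scenario-based modelling of the health and economic benefits of
    reducing the prevalence of physical inactivity in an adult population.
    Converts an absolute prevalence-reduction target into an impact fraction,
    applies it to attributable burden-of-disease tables (incident cases,
    deaths, DALYs, health-sector costs, production losses), and values paid
    production gains under the friction-cost and human-capital approaches,
    unpaid household production at replacement cost and leisure time at an
    opportunity-cost wage fraction, with lifetime discounting and Monte Carlo
    uncertainty propagation. Ships a calibrated synthetic-data generator that
    emulates national survey and burden-of-disease inputs so the full pipeline
    is reproducible without restricted microdata.
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
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
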