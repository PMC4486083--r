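Package: ssbduty
Title: Health Impact Modelling of a Sugar-Sweetened Beverage Duty in England
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Models the population health impact of an ad valorem duty on
    sugar-sweetened beverages (SSBs) in England. Converts a duty rate into a
    per-person daily calorie reduction by age and gender via price elasticity
    of demand, scales the net calorie change pro rata to annual changes in
    diabetes, coronary heart disease and stroke, cancer incidence, quality
    adjusted life years (QALYs), and healthcare costs, propagates parameter
    uncertainty with Monte Carlo simulation, and disaggregates national
    results to lower-tier local authorities weighted by each area's
    demographic structure. Ships the model parameter tables as built-in
    fixtures and a seedable synthetic population generator so the full
    pipeline runs without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    utils
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
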