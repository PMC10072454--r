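Package: ssbtax
Title: Health-Impact Simulation of Sugar-Sweetened Beverage Taxation in Vietnam
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A tested, reusable implementation of a sugar-sweetened beverage
    (SSB) excise-tax health-impact model for the Vietnamese adult population.
    The pipeline chains a tax-to-retail-price step (ad valorem, volumetric and
    sugar-based specific designs), a linear own-price elasticity demand
    response, sugar and energy-intake accounting, equilibrium energy-to-weight
    conversion by age band and sex, cohort BMI reclassification under Western
    Pacific (WPRO) cut-offs with survey-weighted prevalence estimation, and a
    comparative risk assessment of the type-2-diabetes burden with direct
    treatment-cost savings. Includes a calibrated synthetic-cohort generator
    standing in for restricted survey microdata, Monte Carlo probabilistic
    sensitivity analysis, one-way deterministic sensitivity analysis on the
    price elasticity, and a reproducible scenario pipeline driven by a YAML
    configuration.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    ggplot2,
    generics,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
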