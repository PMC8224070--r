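Package: aphidphen
Title: Temperature-Driven Phenology Forecasting for Woolly Apple Aphid and
    Its Parasitoid Aphelinus mali
Version: 0.1.0
Authors@R:
    person("pcfruit", "Modelling", email = "phenology@example.org",
           role = c("aut", "cre"))
Description: Degree-day and polynomial development-rate phenology models for
    the woolly apple aphid (Eriosoma lanigerum) and its main parasitoid
    (Aphelinus mali) in temperate apple orchards. Fits temperature-dependent
    development-rate curves to constant-temperature rearing data by least
    squares with AIC model comparison, accumulates development over orchard
    temperature series with overwintering initialization rules, simulates
    stochastic cohorts of individuals, extracts predicted event dates (first-
    and second-generation parasitoid adult emergence, first crawler
    migration), and validates predictions against interval-censored field
    monitoring observations by observed-on-predicted regression. A synthetic
    weather and trap-monitoring generator makes the whole pipeline testable
    without external data feeds.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    stats,
    utils
Suggests:
    testthat (>= 3.0.0),
    jsonlite,
    withr
Config/testthat/edition: 3
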