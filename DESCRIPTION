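Package: hatchphen
Title: Degree-Day Phenology of Overwintering Mite Egg Hatch
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for analysing diapause termination and postdiapause
    development of overwintering arthropod eggs, developed around the European
    red mite (Panonychus ulmi). Computes per-arena hatch statistics from
    interval-censored hatch time courses (hatch fraction, median hatch time
    T50), applies the two-flat-observations censoring rule, determines the
    diapause-termination date from sequential field-collection batches, fits
    the linear developmental-rate model rate = a + b * temperature to derive
    the lower temperature threshold (x-intercept) and the degree-day constant
    (reciprocal slope), and forecasts the calendar date of 50% egg hatch by
    accumulating degree-days over a daily weather series. Includes a
    synthetic-data generator for hatch experiments, constant-temperature
    trials and daily weather so the whole pipeline is testable without field
    data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    generics,
    ggplot2,
    jsonlite,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    withr,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
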