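Package: perfusim
Title: Monod-Kinetic Simulation and Analysis of Perfused Stem-Cell Bioreactors
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A digital-twin toolkit for high-density expansion of human
    pluripotent stem cells (hPSCs) grown as aggregates in perfused stirred
    tank bioreactors. Implements a multiplicative Monod-kinetic growth and
    metabolism model (glucose, glutamine, lactate, osmolality and aggregate
    size as rate-modifying variables) integrated over a perfusion feed
    schedule; logarithmic-mean estimators of cell-specific growth,
    consumption and production rates from sampled process data in batch and
    perfused regimes; relative prediction-error statistics for model
    evaluation; power-per-volume impeller-speed scale-up, gassing and
    feed-volume planning calculators; and a synthetic process-data generator
    for end-to-end testing. All user-facing functions take and return tidy
    data frames.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    deSolve,
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
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
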