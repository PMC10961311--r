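Package: atnsubsidy
Title: Allometric Trophic Network Dynamics with Time-Varying Phytoplankton Subsidy
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Simulates bioenergetic food-web (allometric trophic network, ATN)
    dynamics for intertidal communities subsidized by offshore phytoplankton.
    A daily chlorophyll-a time series is scaled to areal biomass and drives the
    food-web phytoplankton node through a one-way pelagic-intertidal mixing
    term, making the system non-autonomous. Includes niche-model food-web and
    pulse-forcing generators, extirpation scanning across mixing rates,
    guild-level coefficient-of-variation reports, and biomass-range summaries.
License: MIT
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    deSolve,
    dplyr,
    generics,
    ggplot2,
    purrr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils,
    yaml
Suggests:
    jsonlite,
    optparse,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
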