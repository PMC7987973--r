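Package: soilheat
Title: Probabilistic Analysis of Soil Respiration Under Heatwaves
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for quantifying how heatwaves change continuous soil CO2
    flux (soil respiration, Rs) records. Implements hour-of-month percentile
    climatologies for heatwave detection from long-term station temperature,
    quantile-based soil-moisture regime classification, kernel conditional
    densities and exceedance probabilities of Rs above its site mean under
    heat and moisture conditions, diel-cycle summaries, multi-site synthesis
    with annualized excess-flux estimates, and a fully seeded synthetic
    weather/moisture/flux generator for end-to-end validation.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends:
    R (>= 4.1)
Imports:
    dplyr,
    readr,
    rlang,
    stats,
    tibble,
    tidyr,
    utils
Suggests:
    ggplot2,
    jsonlite,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
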