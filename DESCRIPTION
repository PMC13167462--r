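Package: hazexposure
Title: Multi-Hazard Extreme-Event Exposure Analysis for Gridded
    Climate-Impact Simulations
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Classifies per-grid-cell extreme climate events -- heatwaves
    via the daily heatwave magnitude index (HWMId), soil-moisture droughts,
    river floods via generalized extreme value return levels, and wildfires
    from annual burned area -- relative to long pre-industrial control
    simulations, and summarises the results as 30-year-window event
    frequencies, multi-hazard co-occurrence counts, and area- and
    overlap-weighted exposure of species geographic ranges and ecoregions
    across an ensemble of climate-model by impact-model combinations.
    Includes a seeded synthetic-forcing generator that emulates gridded
    impact-model output (stationary control runs, trend-injected scenario
    runs, pseudo model ensembles, species range masks and ecoregion
    partitions) so the full pipeline runs and is testable offline.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    jsonlite,
    stats,
    utils,
    yaml
LinkingTo:
    Rcpp
Suggests:
    mgcv,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
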