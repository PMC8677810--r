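Package: rasoxy
Title: Dissolved Oxygen Budget and Bioenergetic Growth Simulation for
    Recirculating Tilapia Aquaculture
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Couples an hourly dissolved-oxygen mass balance for a
    recirculating aquaculture system (fish respiration, nitrification,
    biofilter demand and pipe-flow aeration) with a daily bioenergetic
    growth model for Nile tilapia (temperature, dissolved oxygen,
    unionized ammonia and photoperiod limitation factors).  Provides a
    grid calibration of the relative feeding level against a reference
    feeding schedule, parity-regression validation of predicted against
    measured sensor series, and a synthetic sensor/weighing log
    generator so the full validation pipeline can be exercised without
    farm data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    jsonlite,
    stats,
    tools,
    utils,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
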