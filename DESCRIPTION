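Package: thermaldev
Title: Degree-Day Models, Life Tables and Phenology Forecasting for
    Insect Development
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"),
    email = "author@example.org")
Description: Tools for the thermal biology of ectotherm development,
    built around the law of effective temperature. Estimates
    developmental threshold temperatures and thermal constants
    (effective accumulative temperatures) from constant-temperature
    rearing experiments by least squares, models stage survival against
    temperature with a cubic response curve and locates the optimum
    temperature, constructs experimental population life tables with an
    index of population trend, and forecasts voltinism (generations per
    year) and adult emergence peaks from daily or monthly temperature
    records by degree-day accumulation. A seeded synthetic-data module
    simulates rearing experiments and annual weather series so the whole
    pipeline can be exercised without external data; its defaults
    emulate a five-temperature rearing study of the maize pest moth
    Athetis lepigone.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    graphics,
    jsonlite,
    stats,
    utils
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
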