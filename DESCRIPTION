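Package: phenorisk
Title: Degree-Day Phenology and Climatic Suitability Mapping for Emerald Ash Borer
Version: 0.1.0
Authors@R:
    person("phenorisk", "developers", email = "phenorisk@example.org",
           role = c("aut", "cre"))
Description: Spatialized, cohort-structured degree-day phenology model and
    thermal-stress climatic suitability classifier for emerald ash borer
    (Agrilus planipennis). Daily single-triangle degree-day accumulation
    drives a univoltine life-cycle simulation across time-distributed
    overwintering cohorts, mapping day-of-year grids for five phenological
    events (pupation, adult emergence, oviposition, egg hatch, J-larval
    formation). Daily cold and heat stress units classify each grid cell
    into none/moderate/severe establishment-risk exclusion. Includes a
    seeded synthetic daily-weather generator, model-evaluation statistics
    (MAE, bias, Welch TOST equivalence), per-pixel Mann-Kendall trend
    tests, cohort-parameter calibration by grid search, and plain-text
    raster input/output.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.0)
Imports:
    jsonlite,
    stats,
    utils,
    grDevices,
    graphics,
    tools
Suggests:
    testthat (>= 3.0.0),
    optparse,
    withr
Config/testthat/edition: 3
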