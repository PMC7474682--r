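Package: dielflux
Title: Diel Variability Analysis of Lake Methane Chamber Fluxes
Version: 0.1.0
Authors@R:
    person("dielflux", "maintainers", email = "dielflux@example.org",
           role = c("aut", "cre"))
Description: Tools to analyse day-night (diel) variability of lake methane
    emissions measured with floating chambers. Converts chamber headspace
    concentration time series into CH4 fluxes (with sensor calibration and
    quality screening), segments the timeline into sunrise-to-sunrise diel
    cycles from NOAA solar-position equations, computes time-weighted
    geometric hourly flux profiles and day:night flux ratios, screens
    candidate physical drivers (wind, water-air temperature difference,
    photosynthetically active radiation, atmospheric pressure drops), and
    applies a diel correction factor to daytime-only entries of lake
    emission inventories. A synthetic-data generator with known ground
    truth (multiplicative diel pattern, lognormal AR(1) flux noise,
    episodic ebullition, diel meteorological forcing, and the automated
    flux chamber measurement process) makes every stage testable without
    field data.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    tools,
    jsonlite
Suggests:
    testthat (>= 3.0.0),
    optparse
Config/testthat/edition: 3
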