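Package: shootflux
Title: Shoot-Chamber Methane and Carbon Dioxide Flux Estimation and Driver Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Processes non-steady-state shoot-chamber closures from a closed-loop
    greenhouse-gas analyser into biomass-normalized CH4 and CO2 fluxes. Includes
    automated trimming of unstable closure segments, correction of the water-vapour
    spectral interference on reported dry CH4, linear (CH4) and exponential (CO2)
    concentration fits, empty-chamber background modelling with conditional
    subtraction, a three-sigma method-detection-limit ladder, growing-degree-day
    based needle-biomass phenology, and mixed-model analysis of light and
    temperature as emission drivers (PAR splits, temperature-bin Helmert contrasts,
    compact letter displays). A synthetic-campaign generator provides ground truth
    for every stage.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    lme4,
    multcomp,
    minpack.lm,
    jsonlite,
    yaml
Suggests:
    testthat (>= 3.0.0)
Config/testthat/edition: 3
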