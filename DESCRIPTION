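Package: savannaSim
Title: Grid-Based Ecohydrological Simulation of Savanna Land Use by Grazing and Browsing Herbivores
Version: 0.9.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: A spatially explicit ecohydrological simulation of semi-arid savanna
    vegetation under contrasting herbivore land-use strategies. Couples a daily
    two-layer soil-water bucket model with biweekly wet-season dynamics of plant
    functional strategy types (shrubs, perennial and annual grasses, differentiated
    by trait trade-offs), end-of-season selective biomass removal by grazer- or
    browser-dominated herds, a stochastic daily weather generator, a trait
    sensitivity/calibration harness, and community analytics (richness, Shannon and
    Pielou indices, functional dispersion, factor structure, within-cluster sums of
    squares, transpiration share of evapotranspiration).
License: MIT
Encoding: UTF-8
Depends: R (>= 4.0)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    tools,
    yaml,
    jsonlite
LinkingTo: Rcpp
Suggests: testthat (>= 3.0.0)
Config/testthat/edition: 3
RoxygenNote: 7.3.3
Collate:
    'RcppExports.R'
    'savannaSim-package.R'
    'utils.R'
    'climate.R'
    'terrain.R'
    'soil.R'
    'strategies.R'
    'hydrology.R'
    'vegetation.R'
    'herbivory.R'
    'scenario.R'
    'calibration.R'
    'metrics.R'
    'config.R'
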