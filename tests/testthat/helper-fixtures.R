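# Shared fixtures: small grids, short climates and tiny communities built
# in code at test time.

tinyClimate <- function(years = 2, seed = 11) {
  generateClimate(climateConfig(), years, seed)
}

# A small strategy table with two otherwise-identical perennials that
# differ only in one trait, plus a shrub and an annual.
tinyStrategies <- function(uptake2 = 0.45) {
  st <- assembleStrategyTypes("grazing")
  st <- st[c("per.base", "shr.base", "ann.base"), ]
  twin <- st["per.base", ]
  twin$id <- "per.twin"
  twin$uptakeRate <- uptake2
  out <- rbind(st, twin)
  rownames(out) <- out$id
  out
}

flatDem <- function(nr = 4, nc = 4, cellSize = 5) {
  terrainGrid(1195, cellSize = cellSize, nrow = nr, ncol = nc)
}

slopedDem <- function(nr = 4, nc = 4) {
  terrainGrid(matrix(rev(seq_len(nr * nc)), nr, nc), cellSize = 5,
              nrow = nr, ncol = nc)
}

randomHydroState <- function(nr, nc, soil = soilParams()) {
  list(surface = matrix(runif(nr * nc, 0, 2), nr, nc),
       thetaUpper = matrix(runif(nr * nc, soil@residualWater + 0.005,
                                 soil@fcUpper), nr, nc),
       thetaLower = matrix(runif(nr * nc, soil@residualWater + 0.005,
                                 soil@fcUpper), nr, nc))
}

# storage in a hydro state, mm water column per cell
stateStorage <- function(state, soil) {
  as.numeric(state$surface) +
    as.numeric(state$thetaUpper) * soil@depthUpper +
    as.numeric(state$thetaLower) * soil@depthLower
}

smallScenario <- function(landUse = "grazing", sr = 40, years = 3L,
                          replicates = 1L, nr = 6L, nc = 6L, seed = 5L,
                          ...) {
  scenarioConfig(landUse, stockingRate = sr, years = years,
                 replicates = as.integer(replicates), gridRows = nr,
                 gridCols = nc, masterSeed = as.integer(seed), ...)
}
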