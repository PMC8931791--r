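# End-of-season biomass removal by grazer- or browser-dominated herds.
# Pipeline: cover -> biomass (rain-corrected conversion), herd demand from
# the stocking rate, edible fraction per strategy type, cell-by-cell
# selective removal until the demand is met or the edible pool exhausted,
# then biomass -> cover. Food deficits reduce the number of animals
# available for seed dispersal (effective stocking rate).

#' Rainfall correction factor for the cover-biomass conversion
#'
#' Scales the biomass conversion by the year's precipitation relative to the
#' long-term mean annual precipitation, clipped to \[0.2, 2\].
#'
#' @param annualPrecip precipitation sum of the year, mm.
#' @param mapRef reference mean annual precipitation, mm.
#' @return dimensionless factor in \[0.2, 2\].
#' @export
rainCorrection <- function(annualPrecip, mapRef) {
  if (mapRef <= 0) stop("mapRef must be positive")
  .clip(annualPrecip / mapRef, 0.2, 2.0)
}

#' Convert vegetation cover to aboveground biomass
#'
#' `BM = cover * convBm * cfRain` (kg per cell). Exactly invertible for
#' `cfRain > 0` via [biomassToCover()].
#'
#' @param cover cover fraction(s).
#' @param convBm conversion constant, kg per unit cover per cell.
#' @param cfRain rainfall correction factor from [rainCorrection()].
#' @return biomass, kg.
#' @export
coverToBiomass <- function(cover, convBm, cfRain = 1) {
  cover * convBm * cfRain
}

#' @rdname coverToBiomass
#' @param bm biomass, kg.
#' @export
biomassToCover <- function(bm, convBm, cfRain = 1) {
  if (any(cfRain <= 0)) stop("cfRain must be positive to invert")
  bm / (convBm * cfRain)
}

#' Annual herd biomass demand
#'
#' `demand = bodyWeight * 365 * intakeFrac * (1/sr) * area`: the yearly
#' intake of the animals stocked on `area` hectares at `sr` ha per
#' livestock unit (LSU = 450 kg animal eating 2% of its body weight daily).
#'
#' @param sr stocking rate, ha/LSU (> 0; larger means fewer animals).
#' @param area landscape area, ha.
#' @param bodyWeight live weight per LSU, kg.
#' @param intakeFrac daily intake as a fraction of body weight.
#' @return demand, kg/yr.
#' @examples
#' neededBiomass(40, 2.25)  # 184.78125
#' @export
neededBiomass <- function(sr, area, bodyWeight = 450, intakeFrac = 0.02) {
  if (sr <= 0) stop("stocking rate must be positive")
  if (area < 0) stop("area must be non-negative")
  bodyWeight * 365 * intakeFrac * (1 / sr) * area
}

#' Edible share of a biomass pool
#'
#' The defense parameter gives the defended (non-removable) biomass
#' fraction; the edible share is `bm * (1 - defense)`.
#'
#' @param bm biomass, kg.
#' @param defense defended fraction in \[0, 1\].
#' @return edible biomass, kg.
#' @export
edibleBiomass <- function(bm, defense) {
  if (any(defense < 0 | defense > 1)) stop("defense must lie in [0, 1]")
  bm * (1 - defense)
}

# Allocate `demand` kg within one cell across types proportionally to
# pref * edible, capping each type at its edible pool and redistributing
# the remainder among uncapped types.
.allocateWithinCell <- function(demand, edible, prefs) {
  take <- numeric(length(edible))
  remaining <- demand
  open <- edible > 0 & prefs > 0
  while (remaining > 1e-12 && any(open)) {
    w <- prefs[open] * edible[open]
    if (sum(w) <= 0) break
    share <- remaining * w / sum(w)
    newTake <- pmin(take[open] + share, edible[open])
    granted <- sum(newTake - take[open])
    take[open] <- newTake
    remaining <- remaining - granted
    open <- open & (edible - take) > 1e-12
    if (granted <= 1e-15) break
  }
  take
}

#' Selective removal of edible biomass by herbivores
#'
#' Cells are visited in random order (each at most once per pass). If the
#' remaining demand exceeds a cell's edible total, all of it is removed;
#' otherwise the remaining demand is split across the cell's types in
#' proportion to `pref * edible`. A second pass over the grid is allowed if
#' demand and edible biomass both remain. Deterministic for a fixed RNG
#' state.
#'
#' @param edible matrix (cells x types) of edible biomass, kg.
#' @param demand total demand, kg.
#' @param prefs per-type relative palatability (length = ncol(edible)).
#' @return list with `removed` (matrix, kg), `demand`, `deficit` (kg) and
#'   `effectiveSr` multiplier inputs (`removedTotal`).
#' @export
removeBiomass <- function(edible, demand, prefs) {
  if (demand < 0 || any(edible < 0) || any(prefs < 0))
    stop("negative inputs to removeBiomass")
  removed <- matrix(0, nrow(edible), ncol(edible),
                    dimnames = dimnames(edible))
  remaining <- demand
  for (pass in 1:2) {
    if (remaining <= 1e-12) break
    cellPool <- rowSums(edible - removed)
    candidates <- which(cellPool > 1e-12)
    if (length(candidates) == 0L) break
    order <- sample(candidates)
    for (i in order) {
      if (remaining <= 1e-12) break
      avail <- edible[i, ] - removed[i, ]
      pool <- sum(avail)
      if (pool <= 1e-12) next
      if (remaining >= pool) {
        removed[i, ] <- edible[i, ]
        remaining <- remaining - pool
      } else {
        take <- .allocateWithinCell(remaining, avail, prefs)
        removed[i, ] <- removed[i, ] + take
        remaining <- remaining - sum(take)
      }
    }
  }
  list(removed = removed, demand = demand,
       deficit = max(0, demand - sum(removed)),
       removedTotal = sum(removed))
}

#' Effective stocking rate after food deficits
#'
#' When animals cannot meet their demand, fewer of them contribute to seed
#' dispersal: `effectiveSr = sr * demand / removed` (larger ha/LSU means
#' fewer animals); `Inf` when nothing was removed.
#'
#' @param sr nominal stocking rate, ha/LSU.
#' @param demand annual demand, kg.
#' @param removed biomass actually removed, kg.
#' @return effective stocking rate, ha/LSU.
#' @export
effectiveStocking <- function(sr, demand, removed) {
  if (removed > demand + 1e-9 || removed < 0) stop("need demand >= removed >= 0")
  if (removed <= 0) return(Inf)
  if (demand <= 0) return(sr)
  sr * demand / removed
}

#' Apply one season of herbivory to the vegetation state
#'
#' Runs the full pipeline: cover to biomass with the year's rainfall
#' correction, herd demand from the stocking rate, edible pools from the
#' per-type defense parameters, the selective removal loop, and conversion
#' of removed biomass back to cover. Cover never increases; removal never
#' exceeds the edible (undefended) share.
#'
#' @param cover matrix (cells x types) of cover fractions.
#' @param strategies strategy table matching the columns of `cover`
#'   (supplies `herbivorePref`, `defense`, `convBm`).
#' @param sr stocking rate, ha/LSU.
#' @param areaHa landscape area, ha.
#' @param cfRain rainfall correction factor for the biomass conversion.
#' @param staticTypes ids of types whose cover is frozen (excluded from
#'   removal).
#' @param bodyWeight,intakeFrac herd parameters passed to
#'   [neededBiomass()].
#' @return list with `cover` (after removal), `outcome` (demand, removed
#'   matrix and total, deficit, effectiveSr).
#' @export
applyHerbivory <- function(cover, strategies, sr, areaHa, cfRain,
                           staticTypes = character(), bodyWeight = 450,
                           intakeFrac = 0.02) {
  demand <- neededBiomass(sr, areaHa, bodyWeight, intakeFrac)
  convBm <- rep(strategies$convBm, each = nrow(cover))
  bm <- cover * convBm * cfRain
  defense <- rep(strategies$defense, each = nrow(cover))
  edible <- bm * (1 - defense)
  edible[, strategies$id %in% staticTypes] <- 0
  res <- removeBiomass(edible, demand, strategies$herbivorePref)
  newCover <- cover - res$removed / (convBm * cfRain)
  newCover <- pmax(newCover, 0)
  list(cover = newCover,
       outcome = list(demand = demand, removed = res$removed,
                      removedTotal = res$removedTotal,
                      deficit = res$deficit,
                      effectiveSr = effectiveStocking(sr, demand,
                                                      res$removedTotal)))
}
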