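---
title: "A grid-based ecohydrological model of savanna land use by grazers and browsers"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{A grid-based ecohydrological model of savanna land use}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

# Scope and model overview

`savannaSim` simulates a semi-arid savanna landscape of 30 x 30 grid cells
(5 x 5 m each, 2.25 ha) over decades to centuries, under land use dominated
either by grazing herbivores (cattle-like, preferring grasses) or by
browsing herbivores (preferring woody plants). Two dynamically coupled
submodels drive the system:

* a **hydrological submodel** with daily resolution: surface water, and
  volumetric soil moisture in two layers (upper 0--200 mm, lower
  200--1000 mm by default), with infiltration, lateral runoff routing,
  percolation, slow downward diffusion, bare-soil evaporation and
  plant transpiration;
* a **vegetation submodel** with biweekly resolution during the wet
  season: transpiration-driven cover growth, seed dispersal,
  moisture-gated establishment, and end-of-season mortality for 21 plant
  strategy types belonging to three meta plant functional types
  (meta-PFTs): shrubs, perennial grasses, and annual grasses.

Herbivory removes biomass selectively once per year at the end of the
growing season (30 April); the herd's annual demand follows from the
stocking rate (ha per livestock unit; one LSU is a 450 kg animal eating 2%
of its body weight daily).

The year is modelled as 365 days starting on 1 July, so the October--April
growing season never straddles a year boundary. The *fixed* growing season
(October--April) governs when mortality and herbivory occur and over which
days water stress is accumulated; the *variable* wet season (from the first
to the last daily rain event of at least 5 mm) governs when the biweekly
vegetation steps run and over which days wet-season soil moisture is
averaged. Both definitions are deliberately kept distinct.

# Synthetic climate

Observed forcing is replaced by a stochastic generator
(`climateConfig()`, `generateClimate()`):

* Rainfall: wet-season days receive rain as independent Bernoulli trials
  (probability 0.25 per day); event depths are gamma distributed
  (shape 0.75) with mean chosen so that the expected annual sum equals the
  configured mean annual precipitation (291.3 mm by default). A yearly
  log-normal wetness multiplier (mean 1, log-sd 0.45) scales event depths;
  its spread was set once so that simulated annual sums cover the
  observed range of roughly 50--840 mm at the site the default
  configuration describes. Dry-season rain is off by default.
* Temperature: daily means follow a seasonal curve through a June minimum
  (19 degC) and an October maximum (29 degC) with an annual mean of 26
  degC, plus independent Gaussian noise (sd 1.5 degC). A plain sinusoid
  cannot satisfy those three constraints (the extremes are four months
  apart and sit asymmetrically around the mean), so the curve is a
  time-warped cosine -- phase runs linearly from the June minimum to the
  October maximum and back -- with a quadratic colour term
  `T = c0 + c1 s + c2 s^2`, `s = cos(phi(d))`, whose coefficients are
  fixed by the three constraints.

The generator emulates seasonality, the long-run mean and the interannual
variability of rainfall. It does not emulate sub-daily storm structure,
wet-day persistence (there is no Markov dependence between days), spatial
rainfall gradients, or trends; passing tests therefore say nothing about
model behaviour under storm-intensity change or rainfall clustering.

# Hydrology

Per cell and day, in this fixed order: precipitation is added to surface
water; infiltration moves water into the upper layer, limited by remaining
storage and by an effective conductivity
`Ksat * (c0 + (1 - c0) * cover)` with bare-soil fraction `c0 = 0.4`
(roots increase porosity); surface water moves to the steepest-descent
neighbour, damped by vegetation roughness `(1 - 0.8 * cover)`, with closed
boundaries (flat or pit cells retain water, so the grid conserves water
exactly); upper-layer excess over field capacity percolates down at a
conductivity-limited rate, and lower-layer excess leaves as deep drainage;
a small constant diffusion (0.05 mm/day) moves water downward when the
upper layer is wetter; evaporation draws the upper layer towards residual
moisture, scaled by the calibrated evaporation constant (0.16, accounting
for soil crusts) and shaded by vegetation `(1 - 0.85 * cover)`;
transpiration finally extracts water from both layers.

Transpiration demand of type *t* in layer *l* is
`PET * cover_t * uptakeRate_t * rootFrac_{t,l} * g(theta_l)`, with `g`
rising linearly from 0 at the type's wilting point to 1 at field capacity.
Annual grasses root only in the upper layer (1.0/0.0), perennials mostly
so (0.7/0.3), shrubs mostly in the deep layer (0.4/0.6). When demand
exceeds the water extractable above the wilting point, all uptake in that
layer is rationed proportionally. Potential evapotranspiration is a
Hargreaves-type form `PET = 0.0023 * Ra(doy) * (T + 17.8)` with a fixed
seasonal radiation proxy for a southern-hemisphere site (maximum at the
December solstice) that folds in a constant diurnal-range term of
`sqrt(8)`; annual PET is then roughly 1400 mm, several times annual
rainfall, as expected for the region.

The exported functions `infiltrate()`, `routeRunoff()`, `evaporate()`,
`transpire()` and `stepDay()` are the reference implementation. The
scenario runner uses a compiled (C++) core that advances many days with
fixed cover; a test asserts that both paths agree to better than 1e-9 mm.
Inside the core, transpiration is factorized over "uptake groups" (types
sharing a wilting point and root profile see identical water-limitation
terms), which is exact, not an approximation.

# Vegetation

Cover is a per-cell budget shared by all types (never above 1). Within the
wet season, every 14 days:

1. **Growth**: `delta cover = tVeg * wue * transpiration * freeSpace`,
   with water-use efficiency `wue = 0.025` cover per mm. The biweekly
   growth cap (`maxGrow`: shrubs 0.002, perennials 0.02, annuals 0.003)
   is a *shared budget per meta-PFT and cell*, not a per-type allowance:
   with 10 shrub subtypes a per-type cap would multiply tenfold and make
   woody expansion structurally unstoppable.
2. **Dispersal**: grass seed input is the weighted mean cover over a
   150 m^2 neighbourhood (the focal cell and its four orthogonal
   neighbours with weight 1, diagonals with 1/4 -- six cells' worth of
   area). Shrubs disperse through a local exponential kernel (e-folding
   one cell, truncated at radius two) scaled by a viable-seedling factor
   of 0.1, plus herbivore-mediated long-distance events whose expected
   number per biweek is proportional to animal density
   (`ldRate = 6` per cell, unit type cover and 1 ha/LSU); food deficits
   reduce the effective animal density and therefore shrub dispersal.
3. **Establishment**: seeds become cover only where the biweekly mean
   upper-layer moisture exceeds the type's wilting point by a margin of
   0.01 (volumetric). Expected increments are
   `pEst * seedBank * freeSpace` (perennials 0.02, shrub seedlings 0.02,
   annuals 0.05), converted to cover by stochastic rounding to a quantum
   of 0.002 so that low-density populations are not truncated to
   extinction.

At the fixed growing-season end, herbivory removes biomass (next section)
and then mortality reduces cover by
`mrd * (b0 + (1 - b0) * stressFrac)` with background share `b0 = 0.25`.
A growing-season day counts as stressed for a type when the uptake ability
`g(theta)` in its *principal rooting layer* falls below 0.25; this makes
shrub stress respond to deep-layer depletion (and hence to shrub density),
which a root-weighted moisture threshold never registered. Annual grasses
die back completely and regrow from a seed bank that persists across dry
seasons (hard-seeded, `seedSurvival = 1`); their seasonal seed production
is `annualSeedYield = 3` per unit dispersed cover. Per-cell cover below
1e-4 is cleared at season end (local extinction floor). Standing cover
reported for a year is the snapshot at the growing-season end *before*
removal and die-back -- annuals would otherwise always be recorded as
zero.

# Strategy types

Three meta-PFTs are subdivided into strategy types along six traits:
biomass production B (`tVeg`), mortality M (`mrd`), palatability P
(`herbivorePref`), defense D (`defense`, the *defended* biomass fraction),
competitive strength for water C (`uptakeRate`), and drought resistance R
(`wiltingPoint`). A two-letter code gives the specialization (capital:
the trait value producing +10% cover) and the trade-off (lowercase: -10%).
`strategyTraitTable()` ships the calibrated values for both land-use
types; `assembleStrategyTypes()` builds the 21-type community
(10 shrub + 8 perennial strategies plus three base types).

The calibration machinery is runnable: `scanParameter()` varies one trait
over +-30% in a simple community (altered type and same-meta base type
dynamic; the other two base types frozen at their initial cover but still
transpiring and occupying space; medium density 40 ha/LSU),
`solveTargetDeviation()` inverts the fitted regression for the value
predicted to give a +-10% cover deviation, using p < 0.05 as the
significance gate. The acceptance suite checks self-consistency: a type
built from the solved +10% value reaches mean last-20-year cover within
+-3 percentage points of 1.1 times the base cover, across 30 climate
replicates (scans use 5 settings per trait).

# Herbivory

At season end, cover converts to biomass `BM = cover * convBm * cfRain`
with `cfRain = clip(annual precipitation / MAP, 0.2, 2)` and conversion
constants of 20 (shrub), 8 (perennial) and 1 (annual) kg per unit cover
per 25 m^2 cell. The herd demand is
`450 kg * 365 * 0.02 / SR * area`. The edible pool of each type is
`BM * (1 - defense)`: the defense parameter is read as the *defended*
fraction, the only orientation consistent with the shipped trait table
(a larger value is beneficial to the plant, and each land use assigns 0.95
to the meta-PFT its herbivores prefer least). Cells are visited in random
order, at most once per pass with a second pass if demand and edible
biomass remain; a cell whose edible total is below the remaining demand is
stripped completely, otherwise the remainder is split within the cell
proportionally to `pref * edible` (capped at each type's pool, with
iterative redistribution -- a parcel-wise brute-force oracle validates
this closed form). Removed biomass converts back to cover exactly.
Unmet demand is recorded as a deficit, and the effective stocking rate
`SR * demand / removed` (fewer fed animals) feeds back only on
herbivore-mediated shrub dispersal, not on next year's demand.

# Free constants and calibration

Trait values, feeding settings, grid and stocking design, the climate
statistics, and the 5 mm wet-season threshold are fixed inputs. The
remaining process constants have no published values; they were fixed
*once*, by a calibration pass that compared 100-year, multi-replicate runs
of the four headline scenarios against the reported community states
(coexistence at all but the high-grazing scenario; perennial collapse and
bush encroachment under high grazing; high perennial cover with sparse
shrubs under browsing), and are documented above with their defaults. All
of them sit in the single YAML configuration (`loadConfig()`), so every
number named in this vignette can be overridden without touching code.

Three structural choices emerged from that calibration and are deliberate
design decisions, not tuning accidents:

* the meta-PFT-level growth cap (see above);
* the principal-rooting-layer stress rule, which bounds shrub density
  through deep-water depletion;
* the persistent annual seed bank, without which annual grasses are
  bistable (they either vanish everywhere or dominate everywhere).

One residual known bias: at the low stocking rate (40 ha/LSU) the
simulated browsing scenario's total cover and transpiration share sit
about one percentage point *below* the grazing scenario rather than
clearly above it; at 20 ha/LSU the orderings are as expected. The
compressed contrast stems from dense packing of the shrub-dominated state
(its standing cover saturates near 90% rather than the low seventies), a
region of behaviour the available process descriptions do not constrain
further.

# Numerical choices

* Water balance closes to better than 1e-9 mm per cell-day (tested over
  randomized 1000-day trajectories); moisture is clamped to
  [residual, porosity] by construction of each flux.
* Establishment uses stochastic rounding, not truncation, to avoid
  systematic extinction bias at low cover.
* Ties in soil calibration (`calibrateSoil()`) resolve to the first
  candidate in scan order; k-means clustering (`clusterWcss()`) uses a
  fixed internal seed with 50 restarts, so results are deterministic.
* RNG discipline: one master seed; each replicate derives a substream
  keyed to its climate series, so permuting replicates permutes outputs
  without changing any value, and identical configuration plus seed
  reproduces runs bit for bit.
* Factor extraction uses the eigendecomposition of the correlation matrix
  without rotation, retaining eigenvalues above 1 capped at two factors;
  the first factor is signed to load positively on shrub and annual
  types. Pielou's J is defined as 0 for a single-type community, and
  natural logarithms are used throughout so J stays in [0, 1].

# Problem sizes used by the tests

Unit tests run on small grids (up to 6 x 6) and short horizons. The
acceptance suite runs the full 30 x 30 grid at 100 years: the qualitative
scenario panel with 10 climate replicates per scenario, and the
calibration self-consistency check with 30 replicates and 5 scan points;
`scripts/acceptance.R` runs the four headline scenarios at the full 30
replicates. These sizes are the package's own choices for routine
verification; all entry points accept larger values.

# Known limitations

* No fire, no grazing within the season, no animal movement or energetics,
  no mixed-feeder herds.
* Process forms for infiltration, growth and mortality are declared
  substitutes honouring the qualitative statements available for the
  system they emulate; absolute covers should be read against the
  calibration above, not as site predictions.
* Hourly rainfall structure and Richards-equation physics are out of
  scope; the bucket model's deep layer receives water only through
  percolation and a small fixed diffusion.
* Shrub and grass canopies share a single per-cell cover budget (no
  vertical layering).
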