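# Plant strategy types: three meta plant functional types (shrub, perennial
# grass, annual grass) differentiated into life-strategy subtypes by paired
# +10%/-10% trait deviations. Six traits carry the trade-offs:
#   B biomass production  (tVeg)         M mortality            (mrd)
#   P palatability        (herbivorePref) D defense             (defense)
#   C water competition   (uptakeRate)    R drought resistance  (wiltingPoint)
# A capital letter marks the specialization (the value producing +10% cover),
# a lowercase letter the trade-off (-10% cover).

.TRAIT_BY_LETTER <- c(B = "tVeg", M = "mrd", P = "herbivorePref",
                      D = "defense", C = "uptakeRate", R = "wiltingPoint")

.PERENNIAL_CODES <- c("Bd", "Bp", "Cb", "Cp", "Pb", "Pr", "Rb", "Rp")
.SHRUB_CODES <- c("Bd", "Bp", "Bc", "Cb", "Db", "Dc", "Dr", "Mb", "Rc", "Rd")

# Meta-PFT process constants (not part of the trait trade-off table):
# biomass conversion kg per unit cover per 25 m2 cell, root fractions per
# soil layer, and the biweekly cover growth cap. Config-overridable.
.META_DEFAULTS <- data.frame(
  meta = c("shrub", "perennial", "annual"),
  convBm = c(20, 8, 1),
  rootUpper = c(0.4, 0.7, 1.0),
  rootLower = c(0.6, 0.3, 0.0),
  maxGrow = c(0.002, 0.02, 0.003),
  stringsAsFactors = FALSE
)

#' Reference trait trade-off table
#'
#' The calibrated default, -10% (trade-off) and +10% (specialization) values
#' of the six traits for perennial grasses and shrubs, separately for land
#' use dominated by grazers and by browsers, plus the annual-grass base
#' parameters. Shipped as the package's built-in reference parameter set so
#' scenarios can be run without repeating the calibration scans.
#'
#' @return data.frame with columns `land_use`, `meta`, `trait` (internal
#'   trait name), `letter`, `default`, `minus10`, `plus10`.
#' @export
strategyTraitTable <- function() {
  row <- function(lu, meta, letter, def, m10, p10)
    data.frame(land_use = lu, meta = meta,
               trait = unname(.TRAIT_BY_LETTER[letter]), letter = letter,
               default = def, minus10 = m10, plus10 = p10,
               stringsAsFactors = FALSE)
  rbind(
    # perennials, grazer-dominated land use
    row("grazing", "perennial", "D", 0.15, 0.125, 0.175),
    row("grazing", "perennial", "P", 1.00, 1.030, 0.970),
    row("grazing", "perennial", "M", 0.54, 0.557, 0.523),
    row("grazing", "perennial", "B", 0.50, 0.484, 0.516),
    row("grazing", "perennial", "C", 0.90, 0.879, 0.921),
    row("grazing", "perennial", "R", 0.077, 0.0774, 0.0766),
    # perennials, browser-dominated land use
    row("browsing", "perennial", "D", 0.95, 0.944, 0.956),
    row("browsing", "perennial", "P", 0.20, 0.898, 0.000),
    row("browsing", "perennial", "M", 0.54, 0.556, 0.524),
    row("browsing", "perennial", "B", 0.50, 0.482, 0.518),
    row("browsing", "perennial", "C", 0.90, 0.876, 0.924),
    row("browsing", "perennial", "R", 0.077, 0.0774, 0.0766),
    # shrubs, grazer-dominated land use
    row("grazing", "shrub", "D", 0.95, 0.924, 0.976),
    row("grazing", "shrub", "P", 0.20, 0.243, 0.157),
    row("grazing", "shrub", "M", 0.12, 0.137, 0.103),
    row("grazing", "shrub", "B", 0.15, 0.143, 0.157),
    row("grazing", "shrub", "C", 0.50, 0.479, 0.521),
    row("grazing", "shrub", "R", 0.076, 0.077, 0.075),
    # shrubs, browser-dominated land use
    row("browsing", "shrub", "D", 0.70, 0.614, 0.786),
    row("browsing", "shrub", "P", 1.00, 1.291, 0.709),
    row("browsing", "shrub", "M", 0.12, 0.136, 0.104),
    row("browsing", "shrub", "B", 0.15, 0.142, 0.158),
    row("browsing", "shrub", "C", 0.50, 0.471, 0.529),
    row("browsing", "shrub", "R", 0.076, 0.083, 0.069),
    # annual grasses: base parameters only (no subtypes)
    row("grazing", "annual", "D", 0.05, NA, NA),
    row("grazing", "annual", "P", 0.60, NA, NA),
    row("browsing", "annual", "D", 0.95, NA, NA),
    row("browsing", "annual", "P", 0.10, NA, NA),
    row("grazing", "annual", "M", 1.00, NA, NA),
    row("grazing", "annual", "B", 0.70, NA, NA),
    row("grazing", "annual", "C", 0.60, NA, NA),
    row("grazing", "annual", "R", 0.077, NA, NA),
    row("browsing", "annual", "M", 1.00, NA, NA),
    row("browsing", "annual", "B", 0.70, NA, NA),
    row("browsing", "annual", "C", 0.60, NA, NA),
    row("browsing", "annual", "R", 0.077, NA, NA)
  )
}

.traitDefaults <- function(table, landUse, meta) {
  sub <- table[table$land_use == landUse & table$meta == meta, ]
  if (nrow(sub) == 0L) stop(sprintf("no table entries for %s/%s", landUse, meta))
  absent <- setdiff(unname(.TRAIT_BY_LETTER), sub$trait)
  if (length(absent))
    stop(sprintf("missing table entries for %s/%s: %s", landUse, meta,
                 paste(absent, collapse = ", ")))
  setNames(sub$default, sub$trait)
}

.traitValue <- function(table, landUse, meta, letter, column) {
  sub <- table[table$land_use == landUse & table$meta == meta &
                 table$letter == toupper(letter), ]
  if (nrow(sub) != 1L)
    stop(sprintf("missing table entry for %s/%s trait %s", landUse, meta,
                 letter))
  v <- sub[[column]]
  if (is.na(v)) stop(sprintf("no %s value for %s/%s trait %s", column,
                             landUse, meta, letter))
  v
}

#' Assemble the full set of plant strategy types
#'
#' Builds the 21 strategy types of the simulated community for one land-use
#' type: 8 perennial-grass and 10 shrub two-letter strategies plus the base
#' type of each of the three meta-PFTs. A two-letter type takes the +10%
#' (specialization) trait value for its capital letter, the -10% (trade-off)
#' value for its lowercase letter, and defaults elsewhere.
#'
#' @param landUse `"grazing"` or `"browsing"`.
#' @param table a trait table as returned by [strategyTraitTable()].
#' @return data.frame with one row per strategy type and columns `id`,
#'   `code`, `meta`, the six traits (`tVeg`, `mrd`, `herbivorePref`,
#'   `defense`, `uptakeRate`, `wiltingPoint`) and the meta-PFT constants
#'   (`convBm`, `rootUpper`, `rootLower`, `maxGrow`).
#' @examples
#' types <- assembleStrategyTypes("grazing")
#' nrow(types)  # 21
#' types[types$id == "per.Rp", c("wiltingPoint", "herbivorePref")]
#' @export
assembleStrategyTypes <- function(landUse = c("grazing", "browsing"),
                                  table = strategyTraitTable()) {
  landUse <- match.arg(landUse)
  oneType <- function(meta, code) {
    traits <- .traitDefaults(table, landUse, meta)
    if (code != "base") {
      spec <- substr(code, 1L, 1L)
      trade <- substr(code, 2L, 2L)
      traits[.TRAIT_BY_LETTER[spec]] <-
        .traitValue(table, landUse, meta, spec, "plus10")
      traits[.TRAIT_BY_LETTER[toupper(trade)]] <-
        .traitValue(table, landUse, meta, trade, "minus10")
    }
    md <- .META_DEFAULTS[.META_DEFAULTS$meta == meta, ]
    prefix <- c(shrub = "shr", perennial = "per", annual = "ann")[[meta]]
    data.frame(id = paste(prefix, code, sep = "."), code = code, meta = meta,
               tVeg = traits[["tVeg"]], mrd = traits[["mrd"]],
               herbivorePref = traits[["herbivorePref"]],
               defense = traits[["defense"]],
               uptakeRate = traits[["uptakeRate"]],
               wiltingPoint = traits[["wiltingPoint"]],
               convBm = md$convBm, rootUpper = md$rootUpper,
               rootLower = md$rootLower, maxGrow = md$maxGrow,
               stringsAsFactors = FALSE)
  }
  out <- rbind(
    do.call(rbind, lapply(.SHRUB_CODES, oneType, meta = "shrub")),
    oneType("shrub", "base"),
    do.call(rbind, lapply(.PERENNIAL_CODES, oneType, meta = "perennial")),
    oneType("perennial", "base"),
    oneType("annual", "base")
  )
  if (anyDuplicated(out$id)) stop("duplicate strategy type codes")
  rownames(out) <- out$id
  out
}

#' Read / write a trait trade-off table as CSV
#'
#' Round-trips the table format of [strategyTraitTable()].
#'
#' @param table a trait table data.frame.
#' @param path file path.
#' @export
writeStrategyTable <- function(table, path) {
  write.csv(table, path, row.names = FALSE, quote = FALSE)
}

#' @rdname writeStrategyTable
#' @export
readStrategyTable <- function(path) {
  read.csv(path, stringsAsFactors = FALSE)
}
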