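# Terrain grid: elevation surface of the simulated landscape.

#' Terrain grid
#'
#' A rectangular elevation grid with square cells.
#'
#' @slot elevation numeric matrix of elevations (m), rows x cols.
#' @slot cellSize cell edge length (m).
#' @export
setClass("TerrainGrid",
  representation(elevation = "matrix", cellSize = "numeric"))

setValidity("TerrainGrid", function(object) {
  msg <- character()
  if (!is.numeric(object@elevation) || !all(is.finite(object@elevation)))
    msg <- c(msg, "elevation must be a finite numeric matrix")
  if (object@cellSize <= 0) msg <- c(msg, "cellSize must be positive")
  if (length(msg)) msg else TRUE
})

#' @describeIn TerrainGrid-class construct a terrain grid.
#' @param elevation numeric matrix (m) or a single value to be recycled.
#' @param cellSize cell edge length in m (default 5).
#' @param nrow,ncol grid shape when `elevation` is a single value.
#' @export
terrainGrid <- function(elevation, cellSize = 5, nrow = 30L, ncol = 30L) {
  if (length(elevation) == 1L)
    elevation <- matrix(elevation, nrow = nrow, ncol = ncol)
  new("TerrainGrid", elevation = elevation, cellSize = as.numeric(cellSize))
}

setMethod("show", "TerrainGrid", function(object) {
  cat(sprintf("TerrainGrid: %d x %d cells of %g x %g m; elevation %.1f-%.1f m\n",
              nrow(object@elevation), ncol(object@elevation),
              object@cellSize, object@cellSize,
              min(object@elevation), max(object@elevation)))
})

#' Bilinearly interpolate a DEM to a finer resolution
#'
#' Refines a coarse elevation grid (e.g. 30 x 30 m satellite DEM) to a finer
#' cell size (e.g. the 5 x 5 m simulation cells) by bilinear interpolation on
#' cell-node coordinates. Corner values are preserved and linear fields are
#' reproduced exactly.
#'
#' @param coarse a [TerrainGrid-class].
#' @param targetCell target cell size (m); must divide `coarse@cellSize`.
#' @return a [TerrainGrid-class] at the target resolution.
#' @export
interpolateDem <- function(coarse, targetCell) {
  stopifnot(is(coarse, "TerrainGrid"))
  ratio <- coarse@cellSize / targetCell
  if (abs(ratio - round(ratio)) > 1e-9)
    stop("targetCell must divide the coarse cell size")
  ratio <- as.integer(round(ratio))
  z <- coarse@elevation
  nr <- nrow(z); nc <- ncol(z)
  # node coordinates in units of coarse cells
  fr <- seq(0, nr - 1, by = 1 / ratio)
  fc <- seq(0, nc - 1, by = 1 / ratio)
  i0 <- pmin(floor(fr), nr - 2); u <- fr - i0
  j0 <- pmin(floor(fc), nc - 2); v <- fc - j0
  if (nr == 1L) { i0 <- rep(0, length(fr)); u <- rep(0, length(fr)) }
  if (nc == 1L) { j0 <- rep(0, length(fc)); v <- rep(0, length(fc)) }
  out <- matrix(0, length(fr), length(fc))
  for (a in seq_along(fr)) {
    r0 <- i0[a] + 1L; r1 <- min(r0 + 1L, nr)
    z00 <- z[r0, pmin(j0 + 1L, nc)]; z01 <- z[r0, pmin(j0 + 2L, nc)]
    z10 <- z[r1, pmin(j0 + 1L, nc)]; z11 <- z[r1, pmin(j0 + 2L, nc)]
    out[a, ] <- (1 - u[a]) * ((1 - v) * z00 + v * z01) +
                u[a] * ((1 - v) * z10 + v * z11)
  }
  terrainGrid(out, cellSize = targetCell)
}

#' Read / write a DEM as ESRI ASCII grid or CSV matrix
#'
#' `readDemAsc` parses a minimal ESRI ASCII (.asc) raster; `writeDemAsc`
#' writes one. `readDemCsv`/`writeDemCsv` round-trip a plain CSV matrix.
#'
#' @param path file path.
#' @param grid a [TerrainGrid-class].
#' @return readers return a [TerrainGrid-class].
#' @export
readDemAsc <- function(path) {
  lines <- readLines(path)
  hdr <- list()
  i <- 1L
  while (grepl("^[A-Za-z]", lines[i])) {
    kv <- strsplit(trimws(lines[i]), "\\s+")[[1L]]
    hdr[[tolower(kv[1L])]] <- as.numeric(kv[2L])
    i <- i + 1L
  }
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               quiet = TRUE)
  z <- matrix(vals, nrow = hdr$nrows, ncol = hdr$ncols, byrow = TRUE)
  terrainGrid(z, cellSize = hdr$cellsize)
}

#' @rdname readDemAsc
#' @export
writeDemAsc <- function(grid, path) {
  stopifnot(is(grid, "TerrainGrid"))
  z <- grid@elevation
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", ncol(z)), sprintf("nrows %d", nrow(z)),
    "xllcorner 0", "yllcorner 0",
    sprintf("cellsize %g", grid@cellSize), "NODATA_value -9999"), con)
  write.table(z, con, row.names = FALSE, col.names = FALSE)
}

#' @rdname readDemAsc
#' @export
readDemCsv <- function(path, cellSize = 5) {
  z <- as.matrix(read.csv(path, header = FALSE))
  dimnames(z) <- NULL
  terrainGrid(z, cellSize = cellSize)
}

#' @rdname readDemAsc
#' @param cellSize cell size (m) to attach when reading a CSV matrix.
#' @export
writeDemCsv <- function(grid, path) {
  stopifnot(is(grid, "TerrainGrid"))
  write.table(grid@elevation, path, sep = ",", row.names = FALSE,
              col.names = FALSE)
}
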