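# Community and water-use analytics: richness with a cover threshold,
# Shannon diversity and Pielou evenness, nonparametric and standardized
# effect sizes, functional dispersion in a reduced trait space, factor
# structure of cover data, k-means cluster tightness, and the transpiration
# share of evapotranspiration.

#' Strategy-type richness with a cover threshold
#'
#' Counts the types whose total cover strictly exceeds the threshold
#' (default 2.5%), excluding residue of near-extinct types.
#'
#' @param coverByType named numeric vector of total cover per type (%).
#' @param thresholdPct exclusion threshold (%, strict).
#' @return integer count.
#' @export
richness <- function(coverByType, thresholdPct = 2.5) {
  if (any(coverByType < 0)) stop("covers must be non-negative")
  sum(coverByType > thresholdPct)
}

#' Shannon diversity and Pielou evenness
#'
#' Applies the richness threshold, normalizes the remaining abundances to
#' proportions, and computes `H = -sum(p_i * ln(p_i))` and `J = H / ln(S)`
#' (natural logarithms; `J = 0` for a single-type community).
#'
#' @param abundances named numeric vector of abundances (total cover %).
#' @param thresholdPct the richness threshold applied before normalization.
#' @return list with `S`, `H`, `J` and the proportions `p`.
#' @export
shannonPielou <- function(abundances, thresholdPct = 2.5) {
  if (sum(abundances) <= 0) stop("all abundances are zero")
  keep <- abundances[abundances > thresholdPct]
  S <- length(keep)
  if (S == 0L) return(list(S = 0L, H = 0, J = 0, p = numeric()))
  p <- keep / sum(keep)
  H <- -sum(ifelse(p > 0, p * log(p), 0))
  J <- if (S > 1L) H / log(S) else 0
  list(S = S, H = H, J = J, p = p)
}

#' Epsilon-squared effect size for a Kruskal-Wallis statistic
#'
#' `e2 = H / ((n^2 - 1) / (n + 1))`, labelled small (< 0.08), medium
#' (0.08-0.26) or large (> 0.26).
#'
#' @param kruskalH the Kruskal-Wallis H (chi-squared) statistic.
#' @param n total number of observations (>= 2).
#' @return list with `e2` and `label`.
#' @export
epsilonSquared <- function(kruskalH, n) {
  if (n < 2) stop("need n >= 2")
  e2 <- kruskalH / ((n^2 - 1) / (n + 1))
  label <- if (e2 < 0.08) "small" else if (e2 <= 0.26) "medium" else "large"
  list(e2 = e2, label = label)
}

#' Cohen's d with pooled standard deviation
#'
#' `(mean(x) - mean(y)) / s_pooled` with the df-weighted pooled variance.
#'
#' @param x,y numeric samples (each >= 2 values).
#' @return standardized mean difference.
#' @export
cohensD <- function(x, y) {
  if (length(x) < 2L || length(y) < 2L) stop("need >= 2 values per sample")
  sp2 <- ((length(x) - 1) * var(x) + (length(y) - 1) * var(y)) /
    (length(x) + length(y) - 2)
  if (sp2 <= 0) stop("zero pooled standard deviation")
  (mean(x) - mean(y)) / sqrt(sp2)
}

#' Functional dispersion (FDis)
#'
#' Abundance-weighted mean Euclidean distance of community members to the
#' abundance-weighted centroid of the trait space.
#'
#' @param coordinates matrix (types x axes) of trait-space coordinates.
#' @param abundances per-type weights (>= 0, at least one positive).
#' @return list with `fdis`, the `centroid`, and per-type `distances`.
#' @export
functionalDispersion <- function(coordinates, abundances) {
  coordinates <- as.matrix(coordinates)
  if (length(abundances) != nrow(coordinates))
    stop("abundances must match rows of coordinates")
  if (any(abundances < 0) || sum(abundances) <= 0)
    stop("need non-negative abundances with a positive sum")
  w <- abundances / sum(abundances)
  centroid <- colSums(coordinates * w)
  d <- sqrt(rowSums(sweep(coordinates, 2L, centroid)^2))
  list(fdis = sum(w * d), centroid = centroid, distances = d)
}

#' Two-factor structure of a cover matrix
#'
#' Eigendecomposition of the correlation matrix of per-type cover
#' observations (principal-axis style, no rotation). Factors with
#' eigenvalues above 1 are retained, capped at two. Loadings are signed so
#' that factor 1 loads positively on the types named in
#' `orientPositive` (conventionally the shrub and annual types).
#'
#' @param coverMatrix observations x types matrix.
#' @param orientPositive character vector of column names used to fix the
#'   sign of each factor.
#' @return list with `loadings` (types x retained factors), `eigenvalues`,
#'   and `retained`.
#' @export
factorStructure <- function(coverMatrix, orientPositive = NULL) {
  coverMatrix <- as.matrix(coverMatrix)
  if (nrow(coverMatrix) < 3L) stop("need at least 3 observations")
  vars <- apply(coverMatrix, 2L, var)
  if (all(vars == 0)) stop("all columns are constant")
  if (any(vars == 0)) {
    warning("dropping constant columns: ",
            paste(colnames(coverMatrix)[vars == 0], collapse = ", "))
    coverMatrix <- coverMatrix[, vars > 0, drop = FALSE]
  }
  if (ncol(coverMatrix) < 2L) stop("need >= 2 types with variance")
  cm <- cor(coverMatrix)
  eig <- eigen(cm, symmetric = TRUE)
  retained <- max(1L, min(2L, sum(eig$values > 1)))
  load <- eig$vectors[, seq_len(retained), drop = FALSE] *
    rep(sqrt(pmax(eig$values[seq_len(retained)], 0)), each = ncol(cm))
  rownames(load) <- colnames(coverMatrix)
  colnames(load) <- paste0("F", seq_len(retained))
  if (!is.null(orientPositive)) {
    ref <- intersect(orientPositive, rownames(load))
    if (length(ref)) {
      for (k in seq_len(ncol(load))) {
        if (sum(load[ref, k]) < 0) load[, k] <- -load[, k]
      }
    }
  }
  list(loadings = load, eigenvalues = eig$values, retained = retained)
}

#' K-means clustering of factor loadings with per-cluster WCSS
#'
#' Deterministic k-means (fixed internal seed, 50 restarts) on type
#' loadings; the within-cluster sum of squared Euclidean distances to the
#' cluster centroid measures cluster tightness.
#'
#' @param loadings types x axes matrix.
#' @param k number of clusters (default 2).
#' @return list with `assignments` (named), `wcss` (per cluster), and
#'   `centers`.
#' @export
clusterWcss <- function(loadings, k = 2L) {
  loadings <- as.matrix(loadings)
  if (k > nrow(loadings)) stop("k exceeds the number of points")
  if (nrow(unique(loadings)) < k) {
    # degenerate: fewer distinct points than clusters
    assign <- as.integer(factor(apply(loadings, 1L, paste, collapse = ",")))
    wcss <- rep(0, length(unique(assign)))
    return(list(assignments = setNames(assign, rownames(loadings)),
                wcss = wcss, centers = unique(loadings)))
  }
  km <- .withSeed(20220318L, function()
    kmeans(loadings, centers = k, nstart = 50L, iter.max = 100L))
  list(assignments = setNames(km$cluster, rownames(loadings)),
       wcss = km$withinss, centers = km$centers)
}

#' Transpiration share of evapotranspiration
#'
#' `100 * T / ET` (%); 0 when `ET = 0`.
#'
#' @param transp transpiration, mm.
#' @param et evapotranspiration, mm (>= transp).
#' @return percentage.
#' @export
waterUse <- function(transp, et) {
  if (any(transp < 0) || any(et < transp)) stop("need ET >= T >= 0")
  ifelse(et > 0, 100 * transp / et, 0)
}

#' Mean soil moisture over the variable wet season
#'
#' @param thetaSeries daily upper-layer soil moisture (vol %) of one year.
#' @param bounds `c(start, end)` from [wetSeasonBounds()], or `NULL`.
#' @return mean vol %, or `NA` when there is no wet season.
#' @export
wetSeasonMoisture <- function(thetaSeries, bounds) {
  if (is.null(bounds)) return(NA_real_)
  window <- thetaSeries[bounds[[1L]]:bounds[[2L]]]
  if (length(window) == 0L) stop("empty wet-season window")
  mean(window)
}
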