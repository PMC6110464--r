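# Internal niche structure: Z-standardization over modelled-presence cells,
# distance to the niche centroid (DC), optimal/suboptimal/marginal zones, and
# record placement within them.

#' Z-standardize an environment matrix
#'
#' Each variable is centred on its mean and divided by its sample (n - 1)
#' standard deviation over the supplied cells, so the niche centroid is the
#' point where every standardized variable equals zero. Constant variables are
#' dropped with a warning.
#'
#' @param cells environment matrix (>= 2 rows).
#' @param center,scale optional pre-computed parameters (named by variable);
#'   used to place *new* points in an existing standardization.
#' @return list with `mean`, `sd` (named numerics) and `z` (the standardized
#'   matrix).
#' @export
standardizeEnv <- function(cells, center = NULL, scale = NULL) {
  if (nrow(cells) < 2L && is.null(center)) stop("need at least 2 cells")
  if (is.null(center)) {
    center <- colMeans(cells)
    scale <- apply(cells, 2L, stats::sd)
    constant <- scale == 0
    if (any(constant)) {
      warning("dropping constant variable(s): ",
              paste(colnames(cells)[constant], collapse = ", "))
      cells <- cells[, !constant, drop = FALSE]
      center <- center[!constant]; scale <- scale[!constant]
      if (ncol(cells) == 0L) stop("no variable left after dropping constants")
    }
  } else {
    cells <- cells[, names(center), drop = FALSE]
  }
  z <- sweep(sweep(cells, 2L, center), 2L, scale, "/")
  list(mean = center, sd = scale, z = z)
}

#' Distance to the niche centroid
#'
#' Euclidean norm of each standardized row: `DC_i = sqrt(sum_j z_ij^2)`. With
#' the centroid at the zero vector, DC = 0 exactly at the centroid.
#'
#' @param z standardized matrix (rows = cells or records).
#' @return non-negative numeric vector of distances.
#' @export
centroidDistance <- function(z) {
  sqrt(rowSums(as.matrix(z)^2))
}

#' Default zone cutoffs
#'
#' Two ascending DC breakpoints separating optimal / suboptimal / marginal
#' zones. The defaults (1.515, 2.95) make the three bands contiguous; they are
#' data-derived conveniences, overridable per analysis (see
#' [buildNicheStructure()]'s `cutoffs = "auto"` for equal-width bands on the
#' observed DC range).
#'
#' @return numeric(2).
#' @export
defaultZoneCutoffs <- function() c(1.515, 2.95)

#' Classify DC values into niche zones
#'
#' Contiguous half-open bands partitioning `[0, Inf)`: optimal `[0, b1]`,
#' suboptimal `(b1, b2]`, marginal `(b2, Inf)` — so every finite DC maps to
#' exactly one zone, and distances beyond any upper bound observed in a study
#' still classify as marginal.
#'
#' @param dc non-negative DC values.
#' @param cutoffs ascending breakpoints `(b1, b2)`.
#' @return integer vector: 1 optimal, 2 suboptimal, 3 marginal (levels in
#'   `zoneLevels()`).
#' @export
classifyZones <- function(dc, cutoffs = defaultZoneCutoffs()) {
  if (any(dc < 0, na.rm = TRUE)) stop("DC values must be non-negative")
  if (length(cutoffs) != 2L || diff(cutoffs) <= 0)
    stop("cutoffs must be two ascending breakpoints")
  zone <- rep(NA_integer_, length(dc))
  zone[dc <= cutoffs[1]] <- 1L
  zone[dc > cutoffs[1] & dc <= cutoffs[2]] <- 2L
  zone[dc > cutoffs[2]] <- 3L
  zone
}

#' Zone level labels
#' @return `c("optimal", "suboptimal", "marginal")` (codes 1, 2, 3).
#' @export
zoneLevels <- function() .ZONE_LEVELS

#' Build the internal structure of a modelled niche
#'
#' Over the map's consensus-presence cells: Z-standardizes the season-mean
#' climate, computes each cell's DC and classifies it into
#' optimal/suboptimal/marginal zones.
#'
#' @param map the season's [SuitabilityMap-class].
#' @param stack the [ClimateStack-class].
#' @param months the season's months.
#' @param cutoffs numeric(2) breakpoints, or `"auto"` for equal-width thirds
#'   of the observed DC range.
#' @return A [NicheStructure-class].
#' @export
buildNicheStructure <- function(map, stack, months,
                                cutoffs = defaultZoneCutoffs()) {
  pres <- which(binaryMap(map), arr.ind = TRUE)
  if (nrow(pres) < 2L) stop("fewer than 2 modelled-presence cells")
  env <- cellEnvMatrix(stack, months, pres)
  std <- standardizeEnv(env)
  dc <- centroidDistance(std$z)
  if (identical(cutoffs, "auto")) {
    b <- max(dc) / 3
    cutoffs <- c(b, 2 * b)
  }
  zone <- classifyZones(dc, cutoffs)
  grid <- map@grid
  dcR <- matrix(NA_real_, grid@nRows, grid@nCols)
  zoneR <- matrix(NA_integer_, grid@nRows, grid@nCols)
  rc <- do.call(rbind, strsplit(rownames(std$z), ":", fixed = TRUE))
  rc <- matrix(as.integer(rc), ncol = 2L)
  dcR[rc] <- dc
  zoneR[rc] <- zone
  new("NicheStructure", grid = grid, mean = std$mean, sd = std$sd,
      cutoffs = cutoffs, dc = dcR, zones = zoneR, months = as.integer(months))
}

#' Place records within a niche's internal structure
#'
#' Each record's climate (its own month's layers by default, so transient
#' records are judged on the conditions they actually experienced) is
#' standardized with the structure's season parameters, its DC computed and a
#' zone assigned. Records outside the modelled climate envelope still classify
#' — they simply get a large DC. Records on nodata are excluded with a
#' warning.
#'
#' @param occ an [OccurrenceSet-class].
#' @param structure a [NicheStructure-class] from [buildNicheStructure()].
#' @param stack the [ClimateStack-class].
#' @param months optional months to average instead of each record's month.
#' @return list with `assignments` (data.frame: id, month, dc, zone) and
#'   `counts` (named integer per zone, summing to the classified records).
#' @export
classifyRecords <- function(occ, structure, stack, months = NULL) {
  rec <- occ@records
  empty <- data.frame(id = character(), month = integer(),
                      dc = numeric(), zone = character(),
                      stringsAsFactors = FALSE)
  if (!nrow(rec)) {
    counts <- stats::setNames(rep(0L, 3L), .ZONE_LEVELS)
    return(list(assignments = empty, counts = counts))
  }
  parts <- list()
  monthsOf <- if (is.null(months)) sort(unique(rec$month)) else NA
  for (grpMonth in if (is.null(months)) monthsOf else list(months)) {
    sub <- if (is.null(months)) occurrenceSet(rec[rec$month %in% grpMonth, , drop = FALSE])
           else occ
    env <- tryCatch(extractEnv(stack, sub, if (is.null(months)) grpMonth else months),
                    error = function(e) NULL)
    if (is.null(env)) next
    z <- standardizeEnv(env, center = structure@mean, scale = structure@sd)$z
    dc <- centroidDistance(z)
    zone <- classifyZones(dc, structure@cutoffs)
    parts[[length(parts) + 1L]] <- data.frame(
      id = rownames(env),
      month = if (is.null(months)) rep(grpMonth, nrow(env)) else NA_integer_,
      dc = dc, zone = .ZONE_LEVELS[zone], stringsAsFactors = FALSE)
    if (!is.null(months)) break
  }
  assignments <- if (length(parts)) do.call(rbind, parts) else empty
  rownames(assignments) <- NULL
  counts <- stats::setNames(
    as.integer(table(factor(assignments$zone, levels = .ZONE_LEVELS))),
    .ZONE_LEVELS)
  list(assignments = assignments, counts = counts)
}
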