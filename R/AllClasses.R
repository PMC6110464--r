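#' @import methods
NULL

#' Georeferenced grid specification
#'
#' Describes the lattice shared by every climate layer in an analysis: grid
#' dimensions, the geographic coordinate of the *outer corner of the top-left
#' cell*, the cell size in decimal degrees, and the nodata sentinel used when
#' the grid is written to disk (in memory nodata cells are `NA`).
#'
#' Cells are half-open: a point on a shared edge belongs to the cell to its
#' south-east, and row 1 is the northernmost row.
#'
#' @slot nRows,nCols grid dimensions (cells).
#' @slot xOrigin,yOrigin longitude/latitude of the top-left outer corner, degrees.
#' @slot cellSize cell edge length, degrees.
#' @slot nodata sentinel written to file for missing cells.
#' @slot crs free-text identifier of the geographic CRS (lon/lat).
#' @export
setClass("GridSpec",
  representation(
    nRows = "integer", nCols = "integer",
    xOrigin = "numeric", yOrigin = "numeric",
    cellSize = "numeric", nodata = "numeric", crs = "character"
  ),
  prototype(nodata = -9999, crs = "EPSG:4326")
)

setValidity("GridSpec", function(object) {
  msg <- character()
  if (length(object@nRows) != 1L || object@nRows < 1L) msg <- c(msg, "nRows must be a single count >= 1")
  if (length(object@nCols) != 1L || object@nCols < 1L) msg <- c(msg, "nCols must be a single count >= 1")
  if (length(object@cellSize) != 1L || !is.finite(object@cellSize) || object@cellSize <= 0)
    msg <- c(msg, "cellSize must be a single positive number")
  if (!is.finite(object@nodata)) msg <- c(msg, "nodata sentinel must be finite")
  if (length(msg)) msg else TRUE
})

#' Construct a GridSpec
#'
#' @param nRows,nCols grid dimensions.
#' @param xOrigin,yOrigin top-left outer corner, degrees.
#' @param cellSize cell size, degrees.
#' @param nodata nodata sentinel for on-disk representation.
#' @param crs CRS identifier (geographic lon/lat assumed).
#' @return A [GridSpec-class] object.
#' @examples
#' GridSpec(10, 10, xOrigin = -110, yOrigin = 50, cellSize = 0.0416)
#' @export
GridSpec <- function(nRows, nCols, xOrigin, yOrigin, cellSize,
                     nodata = -9999, crs = "EPSG:4326") {
  new("GridSpec",
    nRows = as.integer(nRows), nCols = as.integer(nCols),
    xOrigin = as.numeric(xOrigin), yOrigin = as.numeric(yOrigin),
    cellSize = as.numeric(cellSize), nodata = as.numeric(nodata), crs = crs
  )
}

setMethod("show", "GridSpec", function(object) {
  cat(sprintf(
    "GridSpec: %d x %d cells of %g deg, top-left corner (%g, %g), nodata %g\n",
    object@nRows, object@nCols, object@cellSize,
    object@xOrigin, object@yOrigin, object@nodata
  ))
})

.CLIMATE_VARIABLES <- c("tmax", "tmin", "prec")

#' One monthly climate layer
#'
#' A single gridded variable (`tmax`/`tmin` in degrees C, `prec` in mm) for one
#' calendar month. Missing cells are `NA` in memory.
#'
#' @slot grid the shared [GridSpec-class].
#' @slot variable one of `"tmax"`, `"tmin"`, `"prec"`.
#' @slot month calendar month 1-12.
#' @slot values `nRows x nCols` numeric matrix; `NA` marks nodata.
#' @export
setClass("ClimateLayer",
  representation(grid = "GridSpec", variable = "character",
                 month = "integer", values = "matrix")
)

setValidity("ClimateLayer", function(object) {
  msg <- character()
  if (!object@variable %in% .CLIMATE_VARIABLES)
    msg <- c(msg, sprintf("variable must be one of %s", paste(.CLIMATE_VARIABLES, collapse = "/")))
  if (length(object@month) != 1L || object@month < 1L || object@month > 12L)
    msg <- c(msg, "month must be in 1..12")
  if (!all(dim(object@values) == c(object@grid@nRows, object@grid@nCols)))
    msg <- c(msg, "values shape must match the grid")
  if (object@variable == "prec" && any(object@values < 0, na.rm = TRUE))
    msg <- c(msg, "precipitation must be non-negative wherever not nodata")
  if (length(msg)) msg else TRUE
})

#' Construct a ClimateLayer
#' @param grid a [GridSpec-class].
#' @param variable `"tmax"`, `"tmin"` or `"prec"`.
#' @param month calendar month 1-12.
#' @param values numeric matrix, `NA` = nodata.
#' @return A [ClimateLayer-class].
#' @export
climateLayer <- function(grid, variable, month, values) {
  new("ClimateLayer", grid = grid, variable = variable,
      month = as.integer(month), values = values)
}

setMethod("show", "ClimateLayer", function(object) {
  cat(sprintf("ClimateLayer %s month %02d (%d x %d, %d nodata cells)\n",
    object@variable, object@month, object@grid@nRows, object@grid@nCols,
    sum(is.na(object@values))))
})

#' Monthly climate stack
#'
#' The full set of monthly layers used by an analysis, keyed `"<variable>_<mm>"`
#' (e.g. `"tmax_05"`). All layers share one [GridSpec-class]; for any month
#' present all three variables must be present.
#'
#' @slot grid shared [GridSpec-class].
#' @slot layers named list of [ClimateLayer-class] objects.
#' @export
setClass("ClimateStack",
  representation(grid = "GridSpec", layers = "list")
)

.layerKey <- function(variable, month) sprintf("%s_%02d", variable, month)

setValidity("ClimateStack", function(object) {
  msg <- character()
  for (ly in object@layers) {
    if (!is(ly, "ClimateLayer")) return("layers must all be ClimateLayer objects")
    if (!identical(ly@grid, object@grid))
      msg <- c(msg, sprintf("layer %s has a different GridSpec", .layerKey(ly@variable, ly@month)))
  }
  keys <- unname(vapply(object@layers, function(ly) .layerKey(ly@variable, ly@month), ""))
  if (!identical(sort(names(object@layers)), sort(keys)))
    msg <- c(msg, "layer names must match their (variable, month) keys")
  months <- unique(vapply(object@layers, function(ly) ly@month, 1L))
  for (m in months) {
    have <- vapply(.CLIMATE_VARIABLES, function(v) .layerKey(v, m) %in% names(object@layers), TRUE)
    if (!all(have))
      msg <- c(msg, sprintf("month %d present but missing variable(s): %s",
                            m, paste(.CLIMATE_VARIABLES[!have], collapse = ", ")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct a ClimateStack from layers
#' @param layers list of [ClimateLayer-class]; all on one grid, complete
#'   variable triples per month.
#' @return A [ClimateStack-class].
#' @export
climateStack <- function(layers) {
  stopifnot(length(layers) >= 1L)
  names(layers) <- vapply(layers, function(ly) .layerKey(ly@variable, ly@month), "")
  new("ClimateStack", grid = layers[[1L]]@grid, layers = layers)
}

setMethod("show", "ClimateStack", function(object) {
  months <- sort(unique(vapply(object@layers, function(ly) ly@month, 1L)))
  cat(sprintf("ClimateStack: %d layers, months {%s} on a %d x %d grid\n",
    length(object@layers), paste(months, collapse = ","),
    object@grid@nRows, object@grid@nCols))
})

.SEASON_LEVELS <- c("breeding", "winter", "migratory", "excluded")

#' Occurrence records
#'
#' Cleaned presence-only point records. `records` is a data.frame with columns
#' `id`, `lon`, `lat`, `month` and (after [assignSeason()]) `season`.
#'
#' @slot records data.frame of records, input order preserved.
#' @slot provenance free-text description of where the records came from.
#' @export
setClass("OccurrenceSet",
  representation(records = "data.frame", provenance = "character"),
  prototype(provenance = "")
)

setValidity("OccurrenceSet", function(object) {
  msg <- character()
  rec <- object@records
  need <- c("id", "lon", "lat", "month")
  if (!all(need %in% names(rec)))
    msg <- c(msg, sprintf("records must have columns %s", paste(need, collapse = ", ")))
  else {
    if (any(rec$lon < -180 | rec$lon > 180, na.rm = TRUE)) msg <- c(msg, "lon must lie in [-180, 180]")
    if (any(rec$lat < -90 | rec$lat > 90, na.rm = TRUE)) msg <- c(msg, "lat must lie in [-90, 90]")
    if (any(!rec$month %in% 1:12)) msg <- c(msg, "month must lie in 1..12")
    if ("season" %in% names(rec) && !all(rec$season %in% .SEASON_LEVELS))
      msg <- c(msg, sprintf("season must be one of %s", paste(.SEASON_LEVELS, collapse = "/")))
  }
  if (length(msg)) msg else TRUE
})

#' Construct an OccurrenceSet
#' @param records data.frame with `id`, `lon`, `lat`, `month` (and optionally
#'   `season`).
#' @param provenance free text recorded with the set.
#' @return An [OccurrenceSet-class].
#' @export
occurrenceSet <- function(records, provenance = "") {
  records$id <- as.character(records$id)
  records$month <- as.integer(records$month)
  rownames(records) <- NULL
  new("OccurrenceSet", records = records, provenance = provenance)
}

setMethod("show", "OccurrenceSet", function(object) {
  rec <- object@records
  cat(sprintf("OccurrenceSet: %d records", nrow(rec)))
  if ("season" %in% names(rec) && nrow(rec)) {
    tb <- table(factor(rec$season, levels = .SEASON_LEVELS))
    cat(" (", paste(sprintf("%s %d", names(tb), tb), collapse = ", "), ")", sep = "")
  }
  cat("\n")
})

#' Number of records / layers
#' @param x an [OccurrenceSet-class] or [ClimateStack-class].
#' @return integer count.
#' @export
setMethod("length", "OccurrenceSet", function(x) nrow(x@records))

#' One GARP-style rule-set model
#'
#' An ordered list of rules (range, negated-range or logit); prediction is
#' "first matching rule wins", default class absence, so every environmental
#' vector has a defined prediction.
#'
#' @slot rules ordered list of rules (see [fitRuleModel()]).
#' @slot variables variables the model was trained on (post constant-drop).
#' @slot omission training omission rate.
#' @slot commission commission rate over the modelling region (NA until
#'   computed by [selectBestSubset()]).
#' @slot seed RNG seed used for the fit.
#' @export
setClass("RuleSetModel",
  representation(rules = "list", variables = "character",
                 omission = "numeric", commission = "numeric", seed = "integer"),
  prototype(commission = NA_real_)
)

setMethod("show", "RuleSetModel", function(object) {
  kinds <- vapply(object@rules, function(r) r$kind, "")
  cat(sprintf("RuleSetModel: %d rules (%s), training omission %.3f\n",
    length(object@rules), paste(sprintf("%s %d", names(table(kinds)), table(kinds)), collapse = ", "),
    object@omission))
})

#' Best-subsets niche ensemble
#'
#' The `k` best rule-set replicates (lowest omission filter, then commission
#' closest to the survivor median), plus the per-replicate selection log.
#'
#' @slot members list of [RuleSetModel-class], length `k`.
#' @slot selectionLog data.frame: replicate, omission, commission, selected.
#' @slot omissionMax omission filter used (default 0.10).
#' @slot consensus agreement threshold turning member votes into the binary map.
#' @export
setClass("NicheEnsemble",
  representation(members = "list", selectionLog = "data.frame",
                 omissionMax = "numeric", consensus = "integer")
)

setValidity("NicheEnsemble", function(object) {
  om <- vapply(object@members, function(m) m@omission, 1.0)
  if (any(om > object@omissionMax + 1e-12))
    "every member must satisfy the omission bound" else TRUE
})

setMethod("show", "NicheEnsemble", function(object) {
  cat(sprintf(
    "NicheEnsemble: %d members of %d replicates (omission <= %.2f, consensus >= %d votes)\n",
    length(object@members), nrow(object@selectionLog),
    object@omissionMax, object@consensus))
})

#' Ensemble suitability map
#'
#' Per-cell agreement (count of ensemble members voting presence, 0..K) and the
#' binary consensus map. Nodata propagates from the climate inputs.
#'
#' @slot grid the [GridSpec-class].
#' @slot agreement integer matrix of member votes, `NA` = nodata.
#' @slot k number of ensemble members.
#' @slot consensus votes needed for binary presence.
#' @export
setClass("SuitabilityMap",
  representation(grid = "GridSpec", agreement = "matrix",
                 k = "integer", consensus = "integer")
)

setValidity("SuitabilityMap", function(object) {
  if (any(object@agreement > object@k, na.rm = TRUE)) "agreement must be <= k everywhere"
  else if (any(object@agreement < 0, na.rm = TRUE)) "agreement must be >= 0"
  else TRUE
})

setMethod("show", "SuitabilityMap", function(object) {
  b <- binaryMap(object)
  cat(sprintf(
    "SuitabilityMap: %d x %d, agreement 0..%d, %d presence cells at consensus >= %d\n",
    object@grid@nRows, object@grid@nCols, object@k,
    sum(b, na.rm = TRUE), object@consensus))
})

#' Internal niche structure
#'
#' Z-standardization over modelled-presence cells, the distance-to-centroid
#' (DC) raster and the optimal/suboptimal/marginal zone raster.
#'
#' @slot grid the [GridSpec-class].
#' @slot mean,sd per-variable standardization parameters (named numeric).
#' @slot cutoffs two ascending DC breakpoints separating the zones.
#' @slot dc DC raster (`NA` outside modelled presence).
#' @slot zones integer raster: 1 optimal, 2 suboptimal, 3 marginal.
#' @slot months months of the season the structure was built from.
#' @export
setClass("NicheStructure",
  representation(grid = "GridSpec", mean = "numeric", sd = "numeric",
                 cutoffs = "numeric", dc = "matrix", zones = "matrix",
                 months = "integer")
)

setValidity("NicheStructure", function(object) {
  msg <- character()
  if (any(object@sd <= 0)) msg <- c(msg, "standardization sd must be > 0 for every retained variable")
  if (length(object@cutoffs) != 2L || diff(object@cutoffs) <= 0)
    msg <- c(msg, "cutoffs must be two ascending breakpoints")
  if (any(object@dc < 0, na.rm = TRUE)) msg <- c(msg, "dc must be >= 0")
  if (length(msg)) msg else TRUE
})

setMethod("show", "NicheStructure", function(object) {
  zc <- table(factor(object@zones[!is.na(object@zones)], levels = 1:3,
                     labels = .ZONE_LEVELS))
  cat(sprintf(
    "NicheStructure: cutoffs (%.3f, %.3f); cells: %s\n",
    object@cutoffs[1], object@cutoffs[2],
    paste(sprintf("%s %d", names(zc), zc), collapse = ", ")))
})

.ZONE_LEVELS <- c("optimal", "suboptimal", "marginal")

#' Partial ROC evaluation result
#'
#' @slot aucRatio observed AUC ratio (model/chance over the high-sensitivity
#'   region), in `[0, 2]`.
#' @slot pValue fraction of bootstrap ratios <= 1.
#' @slot E omission tolerance used.
#' @slot nBoot,bootFraction bootstrap settings.
#' @slot bootRatios the per-iteration bootstrap ratios.
#' @slot nTest number of usable test records.
#' @export
setClass("PartialROCResult",
  representation(aucRatio = "numeric", pValue = "numeric", E = "numeric",
                 nBoot = "integer", bootFraction = "numeric",
                 bootRatios = "numeric", nTest = "integer")
)

setValidity("PartialROCResult", function(object) {
  if (object@aucRatio < 0 || object@aucRatio > 2) "aucRatio must lie in [0, 2]"
  else if (object@pValue < 0 || object@pValue > 1) "pValue must lie in [0, 1]"
  else TRUE
})

setMethod("show", "PartialROCResult", function(object) {
  cat(sprintf("Partial ROC: AUC ratio = %.3f (E = %.2f), p = %.4g (%d bootstraps, n_test = %d)\n",
    object@aucRatio, object@E, object@pValue, object@nBoot, object@nTest))
})

#' Polar-coordinate climate cloud
#'
#' Each row of an environment matrix is projected to 2-D by treating each
#' variable as a force vector at a fixed angle; the point is the vector sum.
#'
#' @slot points two-column (X, Y) matrix, one row per input row.
#' @slot angles named angles (radians) per variable.
#' @slot scaling per-variable min/max used to scale values to `[0, 1]`.
#' @export
setClass("PolarCloud",
  representation(points = "matrix", angles = "numeric", scaling = "list")
)

setMethod("show", "PolarCloud", function(object) {
  cat(sprintf("PolarCloud: %d points from %d variables (%s)\n",
    nrow(object@points), length(object@angles),
    paste(names(object@angles), collapse = ", ")))
})

#' Alpha-hull niche breadth polygon
#'
#' The alpha-shape of a polar cloud: the union of Delaunay triangles whose
#' circumradius is at most `alpha`. Breadth is its area; `pixelArea` is filled
#' by [breadthOverlap()] on the shared evaluation lattice.
#'
#' @slot triangles kept Delaunay triangles (n x 3 vertex indices).
#' @slot points the cloud's coordinates the indices refer to.
#' @slot alpha alpha radius used.
#' @slot area alpha-shape area in squared polar units.
#' @slot pixelArea occupied-cell count on the last evaluation lattice (NA
#'   before rasterization).
#' @export
setClass("BreadthPolygon",
  representation(triangles = "matrix", points = "matrix", alpha = "numeric",
                 area = "numeric", pixelArea = "numeric"),
  prototype(pixelArea = NA_real_)
)

setValidity("BreadthPolygon", function(object) {
  if (object@area < 0) "area must be >= 0" else TRUE
})

setMethod("show", "BreadthPolygon", function(object) {
  cat(sprintf("BreadthPolygon: %d triangles, alpha = %.4g, area = %.4g%s\n",
    nrow(object@triangles), object@alpha, object@area,
    if (is.na(object@pixelArea)) "" else sprintf(" (%g pixels)", object@pixelArea)))
})

#' Two-axis PCA environment space
#'
#' Principal axes of the pooled, standardized background climate of the two
#' groups being compared, plus the density lattice spanning their scores.
#'
#' @slot rotation loadings for axes 1-2 (variables x 2).
#' @slot center,scale standardization applied before projection.
#' @slot explained explained-variance fractions of the two axes.
#' @slot xlim,ylim lattice extent (covers all background scores with a margin).
#' @slot R lattice resolution (R x R).
#' @export
setClass("PcaEnvSpace",
  representation(rotation = "matrix", center = "numeric", scale = "numeric",
                 explained = "numeric", xlim = "numeric", ylim = "numeric",
                 R = "integer")
)

setMethod("show", "PcaEnvSpace", function(object) {
  cat(sprintf("PcaEnvSpace: axes explain %.1f%% + %.1f%%, %d x %d density lattice\n",
    100 * object@explained[1], 100 * object@explained[2], object@R, object@R))
})

#' Gridded occupancy density for one season
#'
#' Occurrence kernel density corrected by environment availability on the
#' PCA-env lattice, rescaled to sum to one.
#'
#' @slot z R x R non-negative density matrix summing to 1.
#' @slot bandwidth kernel bandwidths used (x, y).
#' @slot nOcc number of occurrence scores.
#' @export
setClass("OccupancyGrid",
  representation(z = "matrix", bandwidth = "numeric", nOcc = "integer")
)

setValidity("OccupancyGrid", function(object) {
  if (any(object@z < 0)) "occupancy densities must be non-negative"
  else if (abs(sum(object@z) - 1) > 1e-9) "occupancy densities must sum to 1"
  else TRUE
})

setMethod("show", "OccupancyGrid", function(object) {
  cat(sprintf("OccupancyGrid: %d x %d, %d occurrences, bandwidth (%.3g, %.3g)\n",
    nrow(object@z), ncol(object@z), object@nOcc,
    object@bandwidth[1], object@bandwidth[2]))
})

#' Niche similarity test result
#'
#' Observed Schoener's D and its randomization null (focal season's records
#' replaced by draws from the pooled records).
#'
#' @slot dObserved observed D in `[0, 1]`.
#' @slot nullD null D values, one per randomization.
#' @slot pValue `(1 + #\{null >= observed\}) / (nReps + 1)`.
#' @slot nReps number of randomizations.
#' @slot direction which season was randomized (`"a_vs_b"` or `"b_vs_a"`).
#' @slot seed RNG seed.
#' @export
setClass("SimilarityResult",
  representation(dObserved = "numeric", nullD = "numeric", pValue = "numeric",
                 nReps = "integer", direction = "character", seed = "integer")
)

setValidity("SimilarityResult", function(object) {
  if (object@dObserved < -1e-12 || object@dObserved > 1 + 1e-12)
    "observed D must lie in [0, 1]"
  else if (any(object@nullD < -1e-12 | object@nullD > 1 + 1e-12))
    "null D values must lie in [0, 1]"
  else TRUE
})

setMethod("show", "SimilarityResult", function(object) {
  cat(sprintf("Similarity test (%s): observed D = %.3f, p = %.3f (%d randomizations)\n",
    object@direction, object@dObserved, object@pValue, object@nReps))
})
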