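#' Grid of a spatial object
#' @param x a [ClimateStack-class], [ClimateLayer-class], [SuitabilityMap-class]
#'   or [NicheStructure-class].
#' @return the object's [GridSpec-class].
#' @export
setGeneric("gridSpec", function(x) standardGeneric("gridSpec"))

#' @rdname gridSpec
#' @export
setMethod("gridSpec", "ClimateStack", function(x) x@grid)
#' @rdname gridSpec
#' @export
setMethod("gridSpec", "ClimateLayer", function(x) x@grid)
#' @rdname gridSpec
#' @export
setMethod("gridSpec", "SuitabilityMap", function(x) x@grid)
#' @rdname gridSpec
#' @export
setMethod("gridSpec", "NicheStructure", function(x) x@grid)

#' Records of an occurrence set
#' @param x an [OccurrenceSet-class].
#' @return data.frame of records in input order.
#' @export
occurrenceRecords <- function(x) x@records

#' Months present in a stack
#' @param x a [ClimateStack-class].
#' @return sorted integer months.
#' @export
stackMonths <- function(x) {
  sort(unique(vapply(x@layers, function(ly) ly@month, 1L)))
}

#' Values of one layer in a stack
#' @param x a [ClimateStack-class].
#' @param variable `"tmax"`, `"tmin"` or `"prec"`.
#' @param month calendar month.
#' @return the layer's value matrix (`NA` = nodata).
#' @export
layerValues <- function(x, variable, month) {
  key <- .layerKey(variable, month)
  if (!key %in% names(x@layers))
    stop("stack has no layer ", key)
  x@layers[[key]]@values
}

#' Agreement and binary views of a suitability map
#' @param x a [SuitabilityMap-class].
#' @return `agreementMap`: integer matrix of member votes; `binaryMap`: logical
#'   matrix of consensus presence (`NA` = nodata).
#' @export
agreementMap <- function(x) x@agreement

#' @rdname agreementMap
#' @export
binaryMap <- function(x) x@agreement >= x@consensus

#' Ensemble accessors
#' @param x a [NicheEnsemble-class].
#' @return `ensembleMembers`: list of [RuleSetModel-class]; `selectionLog`:
#'   per-replicate omission/commission data.frame.
#' @export
ensembleMembers <- function(x) x@members

#' @rdname ensembleMembers
#' @export
selectionLog <- function(x) x@selectionLog

#' Partial ROC accessors
#' @param x a [PartialROCResult-class].
#' @return numeric scalar.
#' @export
aucRatio <- function(x) x@aucRatio

#' p-value of a test result
#' @param x a [PartialROCResult-class] or [SimilarityResult-class].
#' @return the p-value.
#' @export
setGeneric("pValue", function(x) standardGeneric("pValue"))

#' @rdname pValue
#' @export
setMethod("pValue", "PartialROCResult", function(x) x@pValue)
#' @rdname pValue
#' @export
setMethod("pValue", "SimilarityResult", function(x) x@pValue)

#' Niche structure rasters
#' @param x a [NicheStructure-class].
#' @return `dcRaster`: distance-to-centroid matrix; `zoneRaster`: integer zone
#'   matrix (1 optimal, 2 suboptimal, 3 marginal).
#' @export
dcRaster <- function(x) x@dc

#' @rdname dcRaster
#' @export
zoneRaster <- function(x) x@zones

#' Breadth polygon area
#' @param x a [BreadthPolygon-class].
#' @return area in squared polar-coordinate units.
#' @export
breadthArea <- function(x) x@area

#' Similarity result accessors
#' @param x a [SimilarityResult-class].
#' @return `dObserved`: the observed Schoener's D; `nullDistribution`: the
#'   vector of null D values.
#' @export
dObserved <- function(x) x@dObserved

#' @rdname dObserved
#' @export
nullDistribution <- function(x) x@nullD
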