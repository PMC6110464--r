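# Partial-ROC evaluation of a suitability map against held-out records.

# Piecewise-linear (proportion-of-area, sensitivity) curve over the distinct
# agreement thresholds, restricted to sensitivity >= 1 - E; returns the ratio
# of the model AUC to the chance AUC over that region (both by trapezoid).
# Thresholds are taken from the region's distinct values, so the statistic is
# invariant under strictly monotone transformations of the agreement scale.
.pRocRatio <- function(regionVals, testVals, E) {
  thr <- sort(unique(regionVals), decreasing = TRUE)
  # threshold t: predicted present where value >= t
  x <- vapply(thr, function(t) mean(regionVals >= t), 1.0)  # proportion of area
  y <- vapply(thr, function(t) mean(testVals >= t), 1.0)    # sensitivity
  x <- c(0, x); y <- c(0, y)                                # t = +Inf endpoint
  sMin <- 1 - E
  # first curve point at or above the sensitivity floor
  k <- which(y >= sMin)[1L]
  if (is.na(k)) stop("sensitivity never reaches 1 - E; partial ROC undefined")
  if (k > 1L && y[k] > sMin) {
    # interpolate the crossing of y = 1 - E on the incoming segment
    f <- (sMin - y[k - 1L]) / (y[k] - y[k - 1L])
    x0 <- x[k - 1L] + f * (x[k] - x[k - 1L])
    xs <- c(x0, x[k:length(x)]); ys <- c(sMin, y[k:length(y)])
  } else {
    xs <- x[k:length(x)]; ys <- y[k:length(y)]
  }
  if (xs[length(xs)] - xs[1L] <= 0)
    stop("restricted region has zero width; partial ROC undefined")
  dx <- diff(xs)
  modelArea <- sum(dx * (ys[-1L] + ys[-length(ys)]) / 2)
  chanceArea <- (xs[length(xs)]^2 - xs[1L]^2) / 2
  modelArea / chanceArea
}

#' Partial ROC AUC ratio of a suitability map
#'
#' Evaluates a map's agreement surface against held-out test records in the
#' high-sensitivity region only: thresholds run over the distinct agreement
#' values; sensitivity (1 - omission on the test points) is traced against the
#' proportion of area predicted present; the curve is restricted to
#' sensitivity >= `1 - E`; and the AUC ratio is the model area over the chance
#' (1:1 line) area, both by trapezoid. Ratios near 1 are chance-like; the
#' theoretical range is `[0, 2]`. A map that is constant over the region *is*
#' the chance line and returns ratio 1.
#'
#' The bootstrap resamples `ceiling(bootFraction * n)` test points with
#' replacement `nBoot` times; the p-value is the fraction of bootstrap ratios
#' at or below 1.
#'
#' @param map a [SuitabilityMap-class] (its agreement band is used).
#' @param test held-out [OccurrenceSet-class] (>= 5 records on data cells).
#' @param E omission tolerance in `[0, 1)` (default 0.05; logged in the
#'   result).
#' @param nBoot bootstrap iterations (default 1000).
#' @param bootFraction resampling fraction (default 0.5).
#' @param seed integer seed for the bootstrap.
#' @return A [PartialROCResult-class].
#' @export
partialROC <- function(map, test, E = 0.05, nBoot = 1000L, bootFraction = 0.5,
                       seed = 1L) {
  if (E < 0 || E >= 1) stop("E must lie in [0, 1)")
  agreement <- map@agreement
  regionVals <- agreement[!is.na(agreement)]
  rc <- .cellFromXY(map@grid, test@records$lon, test@records$lat)
  testVals <- agreement[rc[!is.na(rc[, 1L]), , drop = FALSE]]
  nDropped <- length(test) - sum(!is.na(testVals))
  if (nDropped > 0)
    warning(nDropped, " test record(s) off the map or on nodata dropped")
  testVals <- testVals[!is.na(testVals)]
  if (length(testVals) < 5L) stop("need at least 5 usable test records")

  if (length(unique(regionVals)) < 2L) {
    # constant suitability: the curve is the chance line by construction
    return(new("PartialROCResult", aucRatio = 1, pValue = 1, E = E,
               nBoot = as.integer(nBoot), bootFraction = bootFraction,
               bootRatios = rep(1, nBoot), nTest = length(testVals)))
  }
  ratio <- .pRocRatio(regionVals, testVals, E)
  nRes <- ceiling(bootFraction * length(testVals))
  boot <- .withSeed(seed, vapply(seq_len(nBoot), function(i) {
    .pRocRatio(regionVals, sample(testVals, nRes, replace = TRUE), E)
  }, 1.0))
  new("PartialROCResult", aucRatio = ratio, pValue = mean(boot <= 1),
      E = E, nBoot = as.integer(nBoot), bootFraction = bootFraction,
      bootRatios = boot, nTest = length(testVals))
}
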