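# Independent brute-force oracle: build the full (area proportion,
# sensitivity) polyline over every threshold, clip it at the sensitivity
# floor, and integrate a fine trapezoid over an approxfun -- a different
# code path from the package's cumulative trapezoid.
bruteForceRatio <- function(regionVals, testVals, E) {
  thr <- sort(unique(regionVals), decreasing = TRUE)
  x <- c(0, vapply(thr, function(t) mean(regionVals >= t), 1.0))
  y <- c(0, vapply(thr, function(t) mean(testVals >= t), 1.0))
  sMin <- 1 - E
  f <- stats::approxfun(x, y, ties = max)
  xcross <- if (y[1] >= sMin) x[1] else {
    k <- which(y >= sMin)[1]
    stats::uniroot(function(v) f(v) - sMin, c(x[k - 1], x[k]),
                   tol = 1e-14)$root
  }
  # exact for a piecewise-linear curve once the fine grid includes every knot
  knots <- sort(unique(c(xcross, x[x >= xcross], 1)))
  mids <- unlist(lapply(seq_len(length(knots) - 1L), function(i)
    seq(knots[i], knots[i + 1L], length.out = 64L)))
  num <- sum((f(mids[-1]) + f(mids[-length(mids)])) / 2 * diff(mids))
  den <- (1 - xcross^2) / 2
  num / den
}

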