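# Shared fixtures: small grids, stacks and occurrence sets built in code.

tinyGrid <- function(nr = 10, nc = 10, cellSize = 0.5) {
  GridSpec(nr, nc, xOrigin = -106, yOrigin = 50, cellSize = cellSize)
}

tinyStack <- function(grid = tinyGrid(), seed = 1, months = 1:12,
                      params = climateParams()) {
  suppressMessages(makeClimateStack(grid, params, seed = seed, months = months))
}

# occurrence set from lon/lat/month vectors
occAt <- function(lon, lat, month, season = NULL) {
  df <- data.frame(id = sprintf("r%03d", seq_along(lon)),
                   lon = lon, lat = lat, month = month,
                   stringsAsFactors = FALSE)
  if (!is.null(season)) df$season <- season
  occurrenceSet(df)
}

# a rule-set model with a fixed single rule, for ensemble plumbing tests
constantModel <- function(vars, presence = TRUE, omission = 0,
                          commission = NA_real_) {
  lo <- stats::setNames(rep(-Inf, length(vars)), vars)
  hi <- stats::setNames(rep(Inf, length(vars)), vars)
  new("RuleSetModel",
      rules = list(list(kind = "range", low = lo, high = hi,
                        predictedClass = if (presence) "presence" else "absence",
                        fitness = 1)),
      variables = vars, omission = omission, commission = commission,
      seed = 0L)
}

# suitability map from a raw agreement matrix
mapFrom <- function(agreement, k, consensus = ceiling(k / 2),
                    grid = GridSpec(nrow(agreement), ncol(agreement),
                                    -106, 50, 0.5)) {
  storage.mode(agreement) <- "integer"
  new("SuitabilityMap", grid = grid, agreement = agreement,
      k = as.integer(k), consensus = as.integer(consensus))
}

# shoelace area of the convex hull of a point matrix -- independent oracle
chullArea <- function(pts) {
  h <- grDevices::chull(pts)
  x <- pts[h, 1L]; y <- pts[h, 2L]
  n <- length(x); j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}
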