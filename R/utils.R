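# Internal helpers: seeded evaluation, per-stage seed derivation, cell math.

# Evaluate expr under a fixed RNG seed, restoring the caller's RNG state.
.withSeed <- function(seed, expr) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(as.integer(seed))
  expr
}

#' Derive a stage seed from a global seed
#'
#' Deterministically maps a global seed and a stage name to a stage-specific
#' seed, so pipeline stages can be rerun in isolation while the whole run stays
#' reproducible under one seed. The result always fits a 32-bit signed integer.
#'
#' @param seed global integer seed.
#' @param stage stage name (character).
#' @return an integer seed in `[0, 2^31 - 2]`.
#' @examples
#' deriveSeed(1, "fit_breeding") != deriveSeed(1, "fit_winter")
#' @export
deriveSeed <- function(seed, stage) {
  h <- as.double(seed) %% 2147483647
  for (ch in utf8ToInt(stage)) h <- (h * 31 + ch) %% 2147483647
  as.integer(h)
}

# Map lon/lat to (row, col). Half-open cells: a point on a shared edge belongs
# to the cell to its south-east; row 1 is the northernmost row. Points outside
# the extent get NA.
.cellFromXY <- function(grid, lon, lat) {
  col <- floor((lon - grid@xOrigin) / grid@cellSize) + 1
  row <- floor((grid@yOrigin - lat) / grid@cellSize) + 1
  # north edge of the grid belongs to row 1 (no cell to its south-east exists)
  row[lat == grid@yOrigin] <- 1
  col[lon == grid@xOrigin + grid@nCols * grid@cellSize] <- NA  # east outer edge is outside
  bad <- is.na(row) | is.na(col) | row < 1 | row > grid@nRows | col < 1 | col > grid@nCols
  row[bad] <- NA_integer_
  col[bad] <- NA_integer_
  cbind(row = as.integer(row), col = as.integer(col))
}

# Centre coordinates of cells given (row, col).
.xyFromCell <- function(grid, row, col) {
  cbind(
    lon = grid@xOrigin + (col - 0.5) * grid@cellSize,
    lat = grid@yOrigin - (row - 0.5) * grid@cellSize
  )
}

# Shoelace area of a closed polygon given vertex coordinates.
.polygonArea <- function(x, y) {
  n <- length(x)
  j <- c(n, seq_len(n - 1L))
  abs(sum(x[j] * y - x * y[j])) / 2
}
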