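# PCA-env niche comparison: a two-axis climate space calibrated on both
# seasons' backgrounds, availability-corrected kernel densities of occurrences
# on a shared lattice, Schoener's D, and the record-randomization similarity
# test.

#' Build the two-axis PCA environment space
#'
#' Principal axes of the pooled, standardized background climate of both
#' groups; the density lattice spans the pooled scores with a margin so every
#' background point falls inside it.
#'
#' @param backgroundA,backgroundB environment matrices of the two groups'
#'   modelled conditions (pooled >= 10 rows).
#' @param R lattice resolution (default 100).
#' @param margin lattice margin as a fraction of the score range.
#' @return A [PcaEnvSpace-class].
#' @export
buildPcaEnv <- function(backgroundA, backgroundB, R = 100L, margin = 0.1) {
  pooled <- rbind(backgroundA, backgroundB)
  if (nrow(pooled) < 10L) stop("pooled backgrounds must have at least 10 rows")
  sds <- apply(pooled, 2L, stats::sd)
  if (any(sds == 0)) stop("rank-deficient input: constant variable(s) ",
                          paste(colnames(pooled)[sds == 0], collapse = ", "))
  pca <- stats::prcomp(pooled, center = TRUE, scale. = TRUE)
  scores <- pca$x[, 1:2, drop = FALSE]
  xr <- range(scores[, 1L]); yr <- range(scores[, 2L])
  xr <- xr + c(-1, 1) * margin * diff(xr)
  yr <- yr + c(-1, 1) * margin * diff(yr)
  new("PcaEnvSpace",
      rotation = pca$rotation[, 1:2, drop = FALSE],
      center = pca$center, scale = pca$scale,
      explained = pca$sdev[1:2]^2 / sum(pca$sdev^2),
      xlim = xr, ylim = yr, R = as.integer(R))
}

#' Score climate vectors in a PCA-env space
#'
#' @param space a [PcaEnvSpace-class].
#' @param env environment matrix (same variables the space was built on).
#' @return n x 2 score matrix (axes 1-2).
#' @export
pcaScores <- function(space, env) {
  env <- as.matrix(env)[, rownames(space@rotation), drop = FALSE]
  sweep(sweep(env, 2L, space@center), 2L, space@scale, "/") %*% space@rotation
}

# Gaussian kernel density on the space's lattice; h = NULL uses a
# Silverman-type rule (MASS::bandwidth.nrd) per axis.
.kdeOnSpace <- function(scores, space, h = NULL) {
  if (is.null(h)) {
    h <- c(MASS::bandwidth.nrd(scores[, 1L]), MASS::bandwidth.nrd(scores[, 2L]))
    # degenerate spread: fall back to a small fraction of the lattice extent
    h[h <= 0] <- 0.01 * c(diff(space@xlim), diff(space@ylim))[h <= 0]
  }
  k <- MASS::kde2d(scores[, 1L], scores[, 2L], h = h, n = space@R,
                   lims = c(space@xlim, space@ylim))
  list(z = k$z, h = h)
}

#' Availability-corrected occupancy grid of one season
#'
#' Kernel density of the occurrence scores divided by the kernel density of
#' the season's background scores (occupancy = use over availability), on the
#' space's lattice, then rescaled to sum to one. Cells where either density
#' falls below a small relative floor are set to zero, so far-apart seasons
#' have genuinely disjoint supports.
#'
#' @param occScores occurrence scores (>= 3 rows), from [pcaScores()].
#' @param bgScores background scores of the same season.
#' @param space the shared [PcaEnvSpace-class].
#' @param bandwidth optional kernel bandwidths (x, y); default Silverman's
#'   rule on the occurrence scores.
#' @return An [OccupancyGrid-class].
#' @export
occupancyGrid <- function(occScores, bgScores, space, bandwidth = NULL) {
  if (nrow(occScores) < 3L) stop("need at least 3 occurrence scores")
  o <- .kdeOnSpace(occScores, space, bandwidth)
  e <- .kdeOnSpace(bgScores, space)
  new("OccupancyGrid", z = .occupancy(o$z, e$z), bandwidth = o$h,
      nOcc = nrow(occScores))
}

# availability-corrected, normalized occupancy from two raw density surfaces
.occupancy <- function(oz, ez) {
  oz[oz < max(oz) * 1e-8] <- 0  # relative floor: trim far Gaussian tails
  ez[ez < max(ez) * 1e-8] <- 0
  z <- ifelse(ez > 0, oz / ez, 0)
  s <- sum(z)
  if (s <= 0) stop("occupancy grid is empty (zero bandwidth on a point mass?)")
  z / s
}

#' Schoener's D between two occupancy grids
#'
#' `D = 1 - 0.5 * sum(|z1 - z2|)`, from 0 (complete differentiation) to 1
#' (complete similarity). Symmetric.
#'
#' @param z1,z2 [OccupancyGrid-class] objects (or matrices summing to 1) on
#'   the same lattice.
#' @return D in `[0, 1]`.
#' @export
schoenerD <- function(z1, z2) {
  m1 <- if (is(z1, "OccupancyGrid")) z1@z else z1
  m2 <- if (is(z2, "OccupancyGrid")) z2@z else z2
  if (!all(dim(m1) == dim(m2))) stop("grids must have the same shape")
  1 - 0.5 * sum(abs(m1 - m2))
}

#' Niche similarity test by record randomization
#'
#' Computes the observed Schoener's D between the two seasons' occupancy
#' grids, then builds a null distribution: in each of `nReps` randomizations
#' the focal season's records are replaced by a draw of the same size from the
#' pooled records of both seasons and D is recomputed against the other
#' season's observed grid. The p-value uses the add-one convention,
#' `p = (1 + #\{null D >= observed D\}) / (nReps + 1)`, so similarity greater
#' than chance gives small p; p is never exactly 0.
#'
#' @param occA,occB occurrence environment matrices of seasons A and B.
#' @param bgA,bgB background environment matrices of the two seasons.
#' @param space the shared [PcaEnvSpace-class] (from [buildPcaEnv()] on the
#'   same backgrounds).
#' @param nReps randomizations (default 100).
#' @param direction which season is randomized: `"a_vs_b"` randomizes A.
#' @param bandwidth optional fixed kernel bandwidths.
#' @param seed integer seed.
#' @return A [SimilarityResult-class].
#' @export
similarityTest <- function(occA, occB, bgA, bgB, space, nReps = 100L,
                           direction = c("a_vs_b", "b_vs_a"),
                           bandwidth = NULL, seed = 1L) {
  direction <- match.arg(direction)
  if (nReps < 1L) stop("nReps must be >= 1")
  sA <- pcaScores(space, occA); sB <- pcaScores(space, occB)
  gA <- occupancyGrid(sA, pcaScores(space, bgA), space, bandwidth)
  gB <- occupancyGrid(sB, pcaScores(space, bgB), space, bandwidth)
  dObs <- schoenerD(gA, gB)

  pooled <- rbind(sA, sB)
  focalN <- if (direction == "a_vs_b") nrow(sA) else nrow(sB)
  if (nrow(pooled) < focalN) stop("pooled records smaller than the focal sample")
  focalBg <- pcaScores(space, if (direction == "a_vs_b") bgA else bgB)
  otherGrid <- if (direction == "a_vs_b") gB else gA
  ez <- .kdeOnSpace(focalBg, space)$z  # availability surface is fixed per rep
  nullD <- .withSeed(seed, vapply(seq_len(nReps), function(i) {
    draw <- pooled[sample(nrow(pooled), focalN), , drop = FALSE]
    oz <- .kdeOnSpace(draw, space, bandwidth)$z
    schoenerD(.occupancy(oz, ez), otherGrid@z)
  }, 1.0))
  new("SimilarityResult", dObserved = dObs, nullD = nullD,
      pValue = (1 + sum(nullD >= dObs)) / (nReps + 1),
      nReps = as.integer(nReps), direction = direction,
      seed = as.integer(seed))
}
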