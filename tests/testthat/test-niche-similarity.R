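# small climate-like matrices for PCA-env tests
simEnv <- function(n, mu = c(20, 10, 50), sd = c(3, 3, 10), seed = 1) {
  set.seed(seed)
  matrix(rnorm(3 * n, mean = mu, sd = sd), ncol = 3, byrow = TRUE,
         dimnames = list(NULL, c("tmax", "tmin", "prec")))
}

test_that("the PCA-env space has orthonormal axes and sane variance shares", {
  space <- buildPcaEnv(simEnv(300, seed = 1), simEnv(300, seed = 2))
  rot <- space@rotation
  expect_equal(crossprod(rot), diag(2), tolerance = 1e-9, ignore_attr = TRUE)
  expect_true(all(space@explained >= 0 & space@explained <= 1))
  # two perfectly correlated variables collapse onto one axis
  x <- rnorm(200)
  twoVar <- cbind(a = x, b = 2 * x)
  sp2 <- buildPcaEnv(twoVar[1:100, ], twoVar[101:200, ])
  expect_equal(sp2@explained[1], 1, tolerance = 1e-9)
  expect_equal(sp2@explained[2], 0, tolerance = 1e-9)
  # isotropic input spreads variance evenly
  set.seed(9)
  iso <- matrix(rnorm(15000), ncol = 3, dimnames = list(NULL, c("a", "b", "c")))
  sp3 <- buildPcaEnv(iso[1:2500, ], iso[2501:5000, ])
  expect_true(all(abs(sp3@explained - 1 / 3) < 0.05))
  expect_error(buildPcaEnv(cbind(a = rep(1, 20), b = 1:20),
                           cbind(a = rep(1, 20), b = 1:20)), "constant")
})

test_that("occupancy grids are normalized availability-corrected densities", {
  bg <- simEnv(2000, seed = 3)
  occ <- simEnv(200, mu = c(21, 11, 52), sd = c(1, 1, 4), seed = 4)
  space <- buildPcaEnv(bg[1:1000, ], bg[1001:2000, ])
  g <- occupancyGrid(pcaScores(space, occ), pcaScores(space, bg), space)
  expect_equal(sum(g@z), 1, tolerance = 1e-9)
  expect_true(all(g@z >= 0))
  expect_equal(g@nOcc, 200L)
  # a tight cluster concentrates nearly all mass on few cells
  tight <- simEnv(50, mu = c(20, 10, 50), sd = c(0.1, 0.1, 0.3), seed = 5)
  gt <- occupancyGrid(pcaScores(space, tight), pcaScores(space, bg), space)
  expect_gt(max(gt@z), max(g@z))
  expect_equal(sum(gt@z), 1, tolerance = 1e-9)
})

test_that("occurrences distributed like the background occupy evenly", {
  set.seed(6)
  bg <- simEnv(4000, seed = 7)
  occ <- bg[sample(4000, 1500), ]
  space <- buildPcaEnv(bg[1:2000, ], bg[2001:4000, ])
  g <- occupancyGrid(pcaScores(space, occ), pcaScores(space, bg), space)
  core <- g@z[g@z > max(g@z) * 0.05]
  # occupancy (use over availability) is near-flat over the occupied cells
  expect_lt(max(core) / mean(core), 6)
})

test_that("Schoener's D identities hold", {
  z <- matrix(runif(100), 10, 10); z <- z / sum(z)
  expect_equal(schoenerD(z, z), 1)
  a <- matrix(0, 2, 2); a[1, 1] <- 1
  b <- matrix(0, 2, 2); b[2, 2] <- 1
  expect_equal(schoenerD(a, b), 0)  # disjoint supports: complete differentiation
  expect_equal(schoenerD(matrix(c(1, 0), 1, 2), matrix(c(0.5, 0.5), 1, 2)), 0.5)
  z2 <- matrix(runif(100), 10, 10); z2 <- z2 / sum(z2)
  expect_equal(schoenerD(z, z2), schoenerD(z2, z), tolerance = 1e-12)
  # invariant under a common relabelling of cells
  p <- sample(100)
  expect_equal(schoenerD(matrix(z[p], 10), matrix(z2[p], 10)),
               schoenerD(z, z2), tolerance = 1e-12)
  expect_error(schoenerD(z, matrix(1, 2, 2)), "shape")
})

test_that("far-apart niches give observed D of zero", {
  bgA <- simEnv(800, mu = c(30, 20, 30), seed = 8)
  bgB <- simEnv(800, mu = c(5, -5, 90), seed = 9)
  occA <- simEnv(60, mu = c(30, 20, 30), sd = c(1, 1, 3), seed = 10)
  occB <- simEnv(60, mu = c(5, -5, 90), sd = c(1, 1, 3), seed = 11)
  space <- buildPcaEnv(bgA, bgB)
  r <- similarityTest(occA, occB, bgA, bgB, space, nReps = 5, seed = 1)
  expect_equal(dObserved(r), 0)
})

test_that("the randomization null is calibrated and seeded", {
  bg <- simEnv(1500, seed = 12)
  occA <- bg[1:120, ]; occB <- bg[121:240, ]
  space <- buildPcaEnv(bg[1:750, ], bg[751:1500, ])
  r1 <- similarityTest(occA, occB, bg, bg, space, nReps = 50, seed = 3)
  r2 <- similarityTest(occA, occB, bg, bg, space, nReps = 50, seed = 3)
  expect_identical(nullDistribution(r1), nullDistribution(r2))
  expect_length(nullDistribution(r1), 50L)
  expect_gt(pValue(r1), 0)   # add-one convention: never exactly 0
  expect_lte(pValue(r1), 1)
  expect_true(all(nullDistribution(r1) >= 0 & nullDistribution(r1) <= 1))
  # default replication count follows the published protocol
  expect_equal(eval(formals(similarityTest)$nReps), 100L)
  expect_error(similarityTest(occA[1:2, ], occB, bg, bg, space), "3 occurrence")
})

test_that("observed D decreases as seasonal centroids separate", {
  ds <- vapply(c(0, 2, 4, 6), function(delta) {
    sc <- makeScenario(if (delta == 0) "follower" else "switcher",
                       seed = 31, delta = delta)
    occB <- sampleOccurrences(sc@stack, sc@niches$breeding, seed = 32)
    occW <- sampleOccurrences(sc@stack, sc@niches$winter, seed = 33)
    envB <- extractEnv(sc@stack, occB, c(5, 6))
    envW <- extractEnv(sc@stack, occW, c(12, 1, 2))
    bgB <- cellEnvMatrix(sc@stack, c(5, 6))
    bgW <- cellEnvMatrix(sc@stack, c(12, 1, 2))
    space <- buildPcaEnv(bgB, bgW)
    schoenerD(
      occupancyGrid(pcaScores(space, envB), pcaScores(space, bgB), space),
      occupancyGrid(pcaScores(space, envW), pcaScores(space, bgW), space))
  }, 1.0)
  expect_gt(ds[1], ds[4])               # follower clearly above wide switcher
  expect_true(all(diff(ds) <= 0.05))    # monotone non-increasing (small slack)
})
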