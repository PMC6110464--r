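test_that("noise-free tmax is exactly linear in row within a month", {
  p <- climateParams(tmaxNoise = 0, precNoise = 0)
  st <- tinyStack(tinyGrid(8, 6), months = 3, params = p)
  tm <- layerValues(st, "tmax", 3)
  expect_equal(max(abs(tm - tm[, 1])), 0)          # column-invariant
  expect_equal(unname(diff(tm[, 1])), rep(p$tmaxRowGradient, 7))
})

test_that("the seasonal cycle spans exactly twice its amplitude", {
  p <- climateParams(diurnalNoise = 0)
  st <- tinyStack(months = c(1, 7), params = p)
  d <- layerValues(st, "tmax", 7) - layerValues(st, "tmax", 1)
  expect_equal(max(abs(d - 2 * p$seasonalAmplitude)), 0, tolerance = 1e-9)
  # tmin is tmax shifted by the diurnal offset
  expect_equal(layerValues(st, "tmax", 7) - layerValues(st, "tmin", 7),
               matrix(p$diurnalOffset, 10, 10), tolerance = 1e-12)
})

test_that("stack generation is bit-identical under a seed", {
  a <- tinyStack(seed = 42, months = c(2, 9))
  b <- tinyStack(seed = 42, months = c(2, 9))
  for (k in names(a@layers))
    expect_identical(a@layers[[k]]@values, b@layers[[k]]@values)
  c <- tinyStack(seed = 43, months = 2)
  expect_false(identical(a@layers[["tmax_02"]]@values,
                         c@layers[["tmax_02"]]@values))
})

test_that("negative precipitation is clipped at zero and logged", {
  p <- climateParams(precBase = 5, precAmplitude = 40)
  expect_message(st <- makeClimateStack(tinyGrid(), p, seed = 1, months = 1),
                 "clipped")
  expect_true(all(layerValues(st, "prec", 1) >= 0))
})

test_that("vanishing spread concentrates records on the nearest-centroid cells", {
  st <- tinyStack(tinyGrid(20, 20), months = 5)
  env <- cellEnvMatrix(st, 5)
  ctr <- env[200, ]  # an actual cell's climate: exactly attainable
  sp <- nicheSpec(ctr, c(tmax = 0.05, tmin = 0.05, prec = 0.05), "breeding", 5L, 5L)
  occ <- sampleOccurrences(st, sp, seed = 2)
  drawn <- extractEnv(st, occ, 5)
  d2 <- rowSums(sweep(env, 2, ctr)^2)
  # the 5 drawn cells are among the 5 smallest distances to the centroid
  expect_true(all(rowSums(sweep(drawn, 2, ctr)^2) <= sort(d2)[5] + 1e-9))
})

test_that("a single-record draw carries a month from the requested set", {
  st <- tinyStack(months = c(12, 1, 2))
  sp <- nicheSpec(colMeans(cellEnvMatrix(st, c(12, 1, 2))),
                  c(tmax = 2, tmin = 2, prec = 6), "winter", c(12L, 1L, 2L), 1L)
  occ <- sampleOccurrences(st, sp, seed = 3)
  expect_equal(length(occ), 1L)
  expect_true(occurrenceRecords(occ)$month %in% c(12, 1, 2))
  # determinism
  occ2 <- sampleOccurrences(st, sp, seed = 3)
  expect_identical(occurrenceRecords(occ), occurrenceRecords(occ2))
})

test_that("sampled climate means recover the niche centroid", {
  grid <- GridSpec(120, 120, -106, 50, 0.0416)
  st <- suppressMessages(makeClimateStack(grid, seed = 5))
  env <- cellEnvMatrix(st, c(12, 1, 2))
  ctr <- apply(env, 2, median)
  ctr["tmin"] <- ctr["tmax"] - climateParams()$diurnalOffset  # keep attainable
  spread <- c(tmax = 1.5, tmin = 1.5, prec = 5)
  sp <- nicheSpec(ctr, spread, "winter", c(12L, 1L, 2L), 500L)
  occ <- sampleOccurrences(st, sp, seed = 9)
  got <- colMeans(extractEnv(st, occ, c(12, 1, 2)))
  # independent oracle: the availability-weighted expectation of the draw
  z <- sweep(sweep(env, 2, ctr), 2, spread, "/")
  w <- exp(-0.5 * rowSums(z^2))
  expected <- colSums(env * w) / sum(w)
  se <- apply(env, 2, function(col) sqrt(sum(w * (col - mean(col))^2) / sum(w)) /
                sqrt(500))
  expect_true(all(abs(got - expected) < 2 * se))
  # and the centroid itself is recovered up to availability discreteness
  expect_true(all(abs(got - ctr) < 0.25 * spread))
})

test_that("occurrence density tracks true suitability", {
  st <- tinyStack(tinyGrid(60, 60, 0.05), months = 5)
  env <- cellEnvMatrix(st, 5)
  ctr <- apply(env, 2, median); ctr["tmin"] <- ctr["tmax"] - 10
  sp <- nicheSpec(ctr, c(tmax = 2, tmin = 2, prec = 6), "breeding", 5L, 500L)
  occ <- sampleOccurrences(st, sp, seed = 4)
  rc <- occurrenceRecords(occ)
  z <- sweep(sweep(env, 2, ctr), 2, sp@spread, "/")
  s <- exp(-0.5 * rowSums(z^2))
  drawn <- rep(FALSE, nrow(env))
  names(drawn) <- rownames(env)
  col <- floor((rc$lon - st@grid@xOrigin) / st@grid@cellSize) + 1
  row <- floor((st@grid@yOrigin - rc$lat) / st@grid@cellSize) + 1
  drawn[paste(row, col, sep = ":")] <- TRUE
  expect_gt(suppressWarnings(cor(s, as.numeric(drawn), method = "spearman")), 0)
})

test_that("follower niches share one centroid; switchers sit delta apart", {
  fol <- makeScenario("follower", seed = 11)
  expect_identical(fol@niches$breeding@centroid, fol@niches$winter@centroid)
  for (d in c(2, 6)) {
    sw <- makeScenario("switcher", seed = 11, delta = d)
    gap <- (sw@niches$breeding@centroid - sw@niches$winter@centroid) /
      sw@niches$breeding@spread
    expect_equal(sqrt(sum(gap^2)), d, tolerance = 1e-9)
  }
})

test_that("default scenario counts match the study design", {
  sc <- makeScenario("switcher", seed = 1)
  counts <- vapply(sc@niches, function(n) n@nRecords, 1L)
  expect_equal(unname(counts["breeding"]), 246L)
  expect_equal(unname(counts["winter"]), 83L)
  expect_equal(unname(counts[c("m04", "m09", "m10", "m11")]),
               c(28L, 20L, 33L, 15L))
  occ <- sampleScenario(sc)
  expect_equal(sum(occurrenceRecords(occ)$season == "breeding"), 246L)
  # determinism of the full draw
  expect_identical(occurrenceRecords(occ),
                   occurrenceRecords(sampleScenario(sc)))
})

test_that("widely separated niches occupy disjoint climates", {
  # ground-truth niches placed deep in opposite corners of the realized
  # climate of their seasons (many spreads apart along every variable)
  grid <- GridSpec(120, 120, -106, 50, 0.0416)
  st <- suppressMessages(makeClimateStack(grid, seed = 2))
  spread <- c(tmax = 0.8, tmin = 0.8, prec = 3)
  envB <- cellEnvMatrix(st, c(5, 6)); envW <- cellEnvMatrix(st, c(12, 1, 2))
  ctrW <- apply(envW, 2, quantile, probs = 0.15, names = FALSE)
  ctrB <- apply(envB, 2, quantile, probs = 0.85, names = FALSE)
  ctrW["tmin"] <- ctrW["tmax"] - 10; ctrB["tmin"] <- ctrB["tmax"] - 10
  occB <- sampleOccurrences(st, nicheSpec(ctrB, spread, "breeding", c(5L, 6L), 100L), seed = 21)
  occW <- sampleOccurrences(st, nicheSpec(ctrW, spread, "winter", c(12L, 1L, 2L), 100L), seed = 22)
  eB <- extractEnv(st, occB, c(5, 6)); eW <- extractEnv(st, occW, c(12, 1, 2))
  for (v in c("tmax", "tmin", "prec")) {
    disjoint <- max(eW[, v]) < min(eB[, v]) || max(eB[, v]) < min(eW[, v])
    expect_true(disjoint, label = paste("disjoint", v))
  }
})
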