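test_that("the calibration split partitions records 80/20", {
  occ <- occAt(-106 + runif(100, 0.1, 4.9), 50 - runif(100, 0.1, 4.9),
               month = rep(5, 100))
  sp <- splitCalibration(occ, 0.8, seed = 1)
  expect_equal(length(sp$train), 80L)
  expect_equal(length(sp$test), 20L)
  ids <- c(occurrenceRecords(sp$train)$id, occurrenceRecords(sp$test)$id)
  expect_setequal(ids, occurrenceRecords(occ)$id)
  expect_length(intersect(occurrenceRecords(sp$train)$id,
                          occurrenceRecords(sp$test)$id), 0)
  # identical under the same seed
  sp2 <- splitCalibration(occ, 0.8, seed = 1)
  expect_identical(occurrenceRecords(sp$train), occurrenceRecords(sp2$train))
  # minimal case still leaves a test record
  five <- occAt(-105 - (1:5) * 0.1, rep(49, 5), rep(5, 5))
  sp5 <- splitCalibration(five, 0.8, seed = 2)
  expect_equal(c(length(sp5$train), length(sp5$test)), c(4L, 1L))
  expect_error(splitCalibration(occAt(-105, 49, 5), 0.8), "at least 5")
})

# box-shaped niche: presence uniform inside a per-variable box, background wide
boxData <- function(nPres = 200, nBg = 2000, seed = 7) {
  set.seed(seed)
  pres <- cbind(tmax = runif(nPres, 20, 24), tmin = runif(nPres, 10, 14),
                prec = runif(nPres, 40, 60))
  bg <- cbind(tmax = runif(nBg, 0, 40), tmin = runif(nBg, -10, 30),
              prec = runif(nBg, 0, 120))
  list(pres = pres, bg = bg)
}

test_that("a box-shaped niche is recovered with low training omission", {
  d <- boxData()
  m <- fitRuleModel(d$pres, d$bg, seed = 1)
  expect_lte(m@omission, 0.10)
  # the presence region is a small part of the wide background and its
  # temperature bounds recover the true box
  wide <- cbind(tmax = runif(3000, 0, 40), tmin = runif(3000, -10, 30),
                prec = runif(3000, 0, 120))
  pred <- SeasonalNiche:::.predictRules(m@rules, wide)
  expect_lt(mean(pred), 0.2)
  # majority consensus over replicates trims single-replicate tails: the
  # consensus region's climate box recovers the true box
  reps <- lapply(1:15, function(i) fitRuleModel(d$pres, d$bg, seed = i))
  votes <- Reduce(`+`, lapply(reps, function(r)
    SeasonalNiche:::.predictRules(r@rules, wide)))
  cons <- votes >= 8
  expect_gte(quantile(wide[cons, "tmax"], 0.05, names = FALSE), 20 - 3)
  expect_lte(quantile(wide[cons, "tmax"], 0.95, names = FALSE), 24 + 3)
  expect_gte(quantile(wide[cons, "tmin"], 0.05, names = FALSE), 10 - 3)
  expect_lte(quantile(wide[cons, "tmin"], 0.95, names = FALSE), 14 + 3)
  expect_gte(quantile(wide[cons, "prec"], 0.05, names = FALSE), 40 - 12)
  expect_lte(quantile(wide[cons, "prec"], 0.95, names = FALSE), 60 + 12)
})

test_that("rule-set fits are reproducible under a seed", {
  d <- boxData(nPres = 60, nBg = 400)
  m1 <- fitRuleModel(d$pres, d$bg, seed = 5)
  m2 <- fitRuleModel(d$pres, d$bg, seed = 5)
  expect_identical(m1@rules, m2@rules)
  expect_identical(m1@omission, m2@omission)
})

test_that("constant variables are dropped with a warning", {
  d <- boxData(nPres = 50, nBg = 300)
  d$pres[, "prec"] <- 5; d$bg[, "prec"] <- 5
  expect_warning(m <- fitRuleModel(d$pres, d$bg, seed = 1), "constant")
  expect_equal(m@variables, c("tmax", "tmin"))
})

test_that("best-subsets keeps the k models with commission nearest the median", {
  vars <- c("tmax", "tmin", "prec")
  # synthetic replicate list with known omissions/commissions
  omi <- c(rep(0.05, 10), rep(0.5, 5))
  com <- c(seq(0.1, 1.0, by = 0.1), runif(5))
  reps <- lapply(seq_along(omi), function(i)
    constantModel(vars, omission = omi[i], commission = com[i]))
  env <- matrix(0, 5, 3, dimnames = list(NULL, vars))
  ens <- selectBestSubset(reps, env, omissionMax = 0.10, k = 4)
  got <- sort(which(selectionLog(ens)$selected))
  # brute-force oracle: exhaustive sort among the omission survivors
  surv <- which(omi <= 0.10)
  med <- median(com[surv])
  oracle <- sort(surv[order(abs(com[surv] - med), omi[surv], surv)][1:4])
  expect_identical(got, oracle)
  expect_true(all(vapply(ensembleMembers(ens), function(m) m@omission, 1) <= 0.10))
  expect_error(selectBestSubset(reps, env, omissionMax = 0.01, k = 4), "pass")
})

test_that("identical replicates select any k, all at the median commission", {
  vars <- c("tmax", "tmin", "prec")
  reps <- lapply(1:12, function(i) constantModel(vars, omission = 0, commission = 0.3))
  ens <- selectBestSubset(reps, matrix(0, 2, 3, dimnames = list(NULL, vars)), k = 10)
  expect_length(ensembleMembers(ens), 10L)
  expect_true(all(vapply(ensembleMembers(ens), function(m) m@commission, 1) == 0.3))
})

test_that("a degenerate all-presence ensemble votes presence everywhere", {
  st <- tinyStack(months = 5)
  vars <- c("tmax", "tmin", "prec")
  reps <- lapply(1:3, function(i) constantModel(vars, presence = TRUE))
  ens <- new("NicheEnsemble", members = reps,
             selectionLog = data.frame(replicate = 1:3, omission = 0,
                                       commission = 1, selected = TRUE),
             omissionMax = 0.1, consensus = 2L)
  map <- predictSuitability(ens, st, 5)
  expect_true(all(agreementMap(map) == 3L))
  expect_true(all(binaryMap(map)))
  # prediction is deterministic: repeated calls agree cell-by-cell
  expect_identical(agreementMap(predictSuitability(ens, st, 5)),
                   agreementMap(map))
})

test_that("nodata propagates through prediction", {
  st <- tinyStack(months = 5)
  layers <- st@layers
  layers[["tmax_05"]]@values[3, 4] <- NA_real_
  st <- climateStack(layers)
  ens <- new("NicheEnsemble",
             members = list(constantModel(c("tmax", "tmin", "prec"))),
             selectionLog = data.frame(replicate = 1, omission = 0,
                                       commission = 1, selected = TRUE),
             omissionMax = 0.1, consensus = 1L)
  map <- predictSuitability(ens, st, 5)
  expect_true(is.na(agreementMap(map)[3, 4]))
  expect_equal(sum(is.na(agreementMap(map))), 1L)
})

test_that("geographic overlap arithmetic and degenerate cases", {
  a <- matrix(0L, 10, 10); a[1:5, 1:2] <- 1L          # 10 cells
  b <- matrix(0L, 10, 10); b[1:2, 1:2] <- 1L          # 4 of them
  mA <- mapFrom(a, k = 1, consensus = 1)
  mB <- mapFrom(b, k = 1, consensus = 1)
  ov <- geographicOverlap(mA, mB)
  expect_equal(unname(ov["a_to_b"]), 40)
  expect_equal(unname(ov["b_to_a"]), 100)
  expect_equal(unname(geographicOverlap(mA, mA)), c(100, 100))
  disj <- mapFrom(matrix(c(rep(0L, 50), rep(1L, 50)), 10, 10), 1, 1)
  only <- mapFrom(matrix(c(rep(1L, 50), rep(0L, 50)), 10, 10), 1, 1)
  expect_equal(unname(geographicOverlap(disj, only)), c(0, 0))
  empty <- mapFrom(matrix(0L, 10, 10), 1, 1)
  expect_true(all(is.na(geographicOverlap(empty, empty))))
  # overlap ignores cells that are nodata in either map
  a2 <- a; a2[10, 10] <- NA_integer_
  expect_equal(unname(geographicOverlap(mapFrom(a2, 1, 1), mB)["a_to_b"]), 40)
})
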