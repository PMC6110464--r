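# GARP-like presence-only rule-set models: a genetic algorithm over small
# populations of range / negated-range / logit rules, best-subsets replicate
# selection, and projection onto any month's layers.
#
# The rule grammar, fitness and operators are this package's own documented
# variant of the genetic rule-set family; results that depend on them are
# framed as properties (omission bounds, transferability orderings), never as
# numeric reproduction of any particular desktop implementation.

#' Genetic-algorithm settings
#'
#' @param popSize rules per generation.
#' @param generations maximum generations.
#' @param patience stop after this many generations without best-fitness
#'   improvement.
#' @param maxRules maximum rules kept in the final ordered rule set.
#' @param mutationRate per-offspring probability of a point mutation.
#' @param crossoverRate per-offspring probability of crossover.
#' @param eliteFrac fraction of the population carried over unchanged.
#' @param internalSplit fraction of the data used to generate rules; the
#'   held-out remainder scores rule fitness.
#' @param omissionBias weight of a presence record relative to a background
#'   point when scoring rule accuracy. Values above 1 make the fitness
#'   omission-averse, reflecting the protocol's emphasis on low omission over
#'   low commission.
#' @return named list of settings for [fitRuleModel()].
#' @export
gaParams <- function(popSize = 40L, generations = 30L, patience = 8L,
                     maxRules = 20L, mutationRate = 0.3, crossoverRate = 0.5,
                     eliteFrac = 0.2, internalSplit = 0.7, omissionBias = 3) {
  list(popSize = as.integer(popSize), generations = as.integer(generations),
       patience = as.integer(patience), maxRules = as.integer(maxRules),
       mutationRate = mutationRate, crossoverRate = crossoverRate,
       eliteFrac = eliteFrac, internalSplit = internalSplit,
       omissionBias = omissionBias)
}

# ---- rule grammar ----------------------------------------------------------
# A rule is a list:
#   kind "range":          applies where low <= x <= high on every variable
#   kind "negated_range":  applies where the point falls OUTSIDE that box
#   kind "logit":          applies everywhere; predicts presence where
#                          plogis(intercept + x . coef) >= 0.5
# predictedClass is "presence" or "absence". Rule-set prediction: first
# applicable rule wins; default class is absence.

.ruleApplies <- function(rule, X) {
  if (rule$kind == "logit") return(rep(TRUE, nrow(X)))
  inside <- rep(TRUE, nrow(X))
  for (v in colnames(X))
    inside <- inside & X[, v] >= rule$low[v] & X[, v] <= rule$high[v]
  if (rule$kind == "range") inside else !inside
}

.rulePresence <- function(rule, X) {
  if (rule$kind == "logit") {
    p <- stats::plogis(rule$intercept + as.vector(X %*% rule$coef[colnames(X)]))
    p >= 0.5
  } else {
    rep(rule$predictedClass == "presence", nrow(X))
  }
}

# TRUE where the ordered rule set predicts presence (default absence).
.predictRules <- function(rules, X) {
  pred <- rep(FALSE, nrow(X))
  decided <- rep(FALSE, nrow(X))
  for (rule in rules) {
    ap <- .ruleApplies(rule, X) & !decided
    if (!any(ap)) next
    pred[ap] <- .rulePresence(rule, X[ap, , drop = FALSE])
    decided[ap] <- TRUE
    if (all(decided)) break
  }
  pred
}

# ---- rule generation and variation -----------------------------------------

.randomRangeRule <- function(X, presRows, kind, predictedClass, dontCare = 0.3) {
  vars <- colnames(X)
  lo <- apply(X, 2L, min); hi <- apply(X, 2L, max)
  low <- lo; high <- hi
  for (v in vars) {
    if (stats::runif(1) < dontCare) next  # leave the full range: "don't care"
    src <- if (predictedClass == "presence") X[presRows, v] else X[, v]
    b <- sort(sample(src, 2L, replace = TRUE))
    low[v] <- b[1]; high[v] <- b[2]
  }
  list(kind = kind, low = low, high = high,
       predictedClass = predictedClass, fitness = -Inf)
}

# climate-envelope seed: presence quantiles per variable (part of the random
# initial population, classic data-driven rule seeding)
.envelopeRule <- function(X, presRows, q = c(0.01, 0.99)) {
  P <- X[presRows, , drop = FALSE]
  list(kind = "range",
       low = apply(P, 2L, stats::quantile, probs = q[1], names = FALSE),
       high = apply(P, 2L, stats::quantile, probs = q[2], names = FALSE),
       predictedClass = "presence", fitness = -Inf)
}

.randomLogitRule <- function(X) {
  sds <- apply(X, 2L, stats::sd)
  coef <- stats::rnorm(ncol(X)) / pmax(sds, 1e-9)
  names(coef) <- colnames(X)
  center <- colMeans(X)
  list(kind = "logit", coef = coef,
       intercept = stats::rnorm(1) - sum(coef * center),
       predictedClass = "presence", fitness = -Inf)
}

.initialPopulation <- function(X, presRows, popSize) {
  pop <- list(.envelopeRule(X, presRows), .envelopeRule(X, presRows, c(0.05, 0.95)))
  while (length(pop) < popSize) {
    u <- stats::runif(1)
    pop[[length(pop) + 1L]] <-
      if (u < 0.45) .randomRangeRule(X, presRows, "range", "presence")
      else if (u < 0.6) .randomRangeRule(X, presRows, "range", "absence")
      else if (u < 0.8) .randomRangeRule(X, presRows, "negated_range",
                                         sample(c("presence", "absence"), 1L))
      else .randomLogitRule(X)
  }
  pop
}

.mutateRule <- function(rule, X) {
  vars <- colnames(X)
  if (rule$kind == "logit") {
    v <- sample(vars, 1L)
    rule$coef[v] <- rule$coef[v] + stats::rnorm(1, sd = 0.3 * max(abs(rule$coef[v]), 1e-3))
    if (stats::runif(1) < 0.3)
      rule$intercept <- rule$intercept + stats::rnorm(1, sd = 0.5)
  } else {
    v <- sample(vars, 1L)
    span <- max(X[, v]) - min(X[, v])
    rule$low[v] <- rule$low[v] + stats::rnorm(1, sd = 0.1 * span)
    rule$high[v] <- rule$high[v] + stats::rnorm(1, sd = 0.1 * span)
    if (rule$low[v] > rule$high[v]) {  # keep the interval well-formed
      tmp <- rule$low[v]; rule$low[v] <- rule$high[v]; rule$high[v] <- tmp
    }
  }
  rule$fitness <- -Inf
  rule
}

.crossoverRules <- function(a, b, X) {
  if (a$kind == "logit" || b$kind == "logit") {
    if (a$kind == "logit" && b$kind == "logit") {
      w <- stats::runif(1)
      a$coef <- w * a$coef + (1 - w) * b$coef
      a$intercept <- w * a$intercept + (1 - w) * b$intercept
    }
    a$fitness <- -Inf
    return(a)
  }
  swap <- stats::runif(ncol(X)) < 0.5
  vars <- colnames(X)[swap]
  a$low[vars] <- b$low[vars]
  a$high[vars] <- b$high[vars]
  a$fitness <- -Inf
  a
}

# Fitness: z-score of the rule's accuracy gain over the prior prevalence of
# its predicted class, scored on the held-out internal split. Presence records
# carry `bias` times the weight of background points (omission-averse), so
# absence rules that swallow known presences are penalized. Rules that apply
# to nothing score -Inf.
.ruleFitness <- function(rule, X, y, bias = 1) {
  ap <- .ruleApplies(rule, X)
  n <- sum(ap)
  if (n == 0L) return(-Inf)
  w <- ifelse(y == 1L, bias, 1)
  predPres <- .rulePresence(rule, X[ap, , drop = FALSE])
  correct <- ifelse(predPres, y[ap] == 1L, y[ap] == 0L)
  acc <- sum(w[ap] * correct) / sum(w[ap])
  # weighted chance accuracy of assigning the rule's class at random
  wPres <- sum(w[y == 1L]) / sum(w)
  prior <- mean(ifelse(predPres, wPres, 1 - wPres))
  if (prior <= 0 || prior >= 1) return(-Inf)
  sqrt(n) * (acc - prior) / sqrt(prior * (1 - prior))
}

# ---- model fitting ---------------------------------------------------------

#' Fit one GARP-like rule-set model
#'
#' Runs a genetic algorithm over a population of presence/absence rules
#' (range, negated-range and logit kinds). Fitness is the significance
#' (z-score) of a rule's accuracy gain over prior prevalence on a held-out
#' internal split; operators are point mutation of interval bounds or
#' coefficients, variable-wise crossover, and insertion of fresh random rules;
#' the run stops at `generations` or when the best fitness stagnates for
#' `patience` generations. The final model is the non-redundant rule list
#' ordered by fitness (each kept rule decides at least one point no earlier
#' rule decided). Reproducible under `seed`.
#'
#' @param presence environment matrix of presence records (rows = records).
#' @param background environment matrix of background cells sampled from the
#'   modelling region.
#' @param params settings from [gaParams()].
#' @param seed integer seed.
#' @return A [RuleSetModel-class] with its training omission rate.
#' @export
fitRuleModel <- function(presence, background, params = gaParams(), seed = 1L) {
  if (nrow(presence) < 5L) stop("need at least 5 presence records")
  X <- rbind(presence, background)
  y <- c(rep(1L, nrow(presence)), rep(0L, nrow(background)))
  constant <- apply(X, 2L, function(col) diff(range(col)) == 0)
  if (any(constant)) {
    warning("dropping constant variable(s): ",
            paste(colnames(X)[constant], collapse = ", "))
    X <- X[, !constant, drop = FALSE]
    if (ncol(X) == 0L) stop("no informative variable left")
  }
  vars <- colnames(X)

  model <- .withSeed(seed, {
    inTrain <- sample(nrow(X)) <= params$internalSplit * nrow(X)
    if (!any(y[!inTrain] == 1L) || !any(y[!inTrain] == 0L))
      inTrain <- seq_len(nrow(X)) %% 10 != 0  # degenerate split fallback
    Xg <- X[inTrain, , drop = FALSE]           # rule generation
    Xv <- X[!inTrain, , drop = FALSE]; yv <- y[!inTrain]  # fitness scoring
    presRows <- which(y[inTrain] == 1L)

    bias <- params$omissionBias
    pop <- .initialPopulation(Xg, presRows, params$popSize)
    pop <- lapply(pop, function(r) { r$fitness <- .ruleFitness(r, Xv, yv, bias); r })
    best <- max(vapply(pop, function(r) r$fitness, 1.0))
    stale <- 0L
    nElite <- max(1L, round(params$eliteFrac * params$popSize))

    for (gen in seq_len(params$generations)) {
      ord <- order(vapply(pop, function(r) r$fitness, 1.0), decreasing = TRUE)
      pop <- pop[ord]
      offspring <- pop[seq_len(nElite)]
      while (length(offspring) < params$popSize) {
        # binary tournament selection
        i <- min(sample(params$popSize, 2L)); j <- min(sample(params$popSize, 2L))
        child <- pop[[i]]
        if (stats::runif(1) < params$crossoverRate)
          child <- .crossoverRules(child, pop[[j]], Xg)
        if (stats::runif(1) < params$mutationRate)
          child <- .mutateRule(child, Xg)
        if (stats::runif(1) < 0.05)  # rule insertion keeps diversity
          child <- if (stats::runif(1) < 0.8)
            .randomRangeRule(Xg, presRows, "range", "presence")
          else .randomLogitRule(Xg)
        if (is.infinite(child$fitness))
          child$fitness <- .ruleFitness(child, Xv, yv, bias)
        offspring[[length(offspring) + 1L]] <- child
      }
      pop <- offspring
      newBest <- max(vapply(pop, function(r) r$fitness, 1.0))
      if (newBest > best + 1e-9) { best <- newBest; stale <- 0L }
      else stale <- stale + 1L
      if (stale >= params$patience) break
    }

    # non-redundant assembly with incorporation-or-rejection: walking down the
    # fitness order, a rule is kept only if, on the points no earlier rule
    # decided, its predictions beat the prior prevalence of its class
    ord <- order(vapply(pop, function(r) r$fitness, 1.0), decreasing = TRUE)
    pop <- pop[ord]
    decided <- rep(FALSE, nrow(X))
    wAll <- ifelse(y == 1L, bias, 1)
    wPres <- sum(wAll[y == 1L]) / sum(wAll)
    rules <- list()
    for (rule in pop) {
      if (length(rules) >= params$maxRules || all(decided)) break
      if (rule$fitness <= 0) break  # no better than chance: default to absence
      ap <- .ruleApplies(rule, X) & !decided
      if (!any(ap)) next
      predPres <- .rulePresence(rule, X[ap, , drop = FALSE])
      correct <- ifelse(predPres, y[ap] == 1L, y[ap] == 0L)
      acc <- sum(wAll[ap] * correct) / sum(wAll[ap])
      prior <- mean(ifelse(predPres, wPres, 1 - wPres))
      if (acc <= prior) next  # rejection: no marginal gain
      decided <- decided | ap
      rules[[length(rules) + 1L]] <- rule
    }
    rules
  })

  omission <- 1 - mean(.predictRules(model, X[y == 1L, , drop = FALSE]))
  new("RuleSetModel", rules = model, variables = vars,
      omission = omission, commission = NA_real_, seed = as.integer(seed))
}

#' Split records into calibration and evaluation sets
#'
#' Random seeded partition: `round(fraction * n)` training records, the rest
#' for testing; disjoint, union = input, input order preserved within each
#' part.
#'
#' @param occ an [OccurrenceSet-class] (>= 5 records).
#' @param fraction training fraction in (0, 1) (default 0.8).
#' @param seed integer seed.
#' @return list with elements `train` and `test`.
#' @export
splitCalibration <- function(occ, fraction = 0.8, seed = 1L) {
  n <- length(occ)
  if (n < 5L) stop("need at least 5 records to split")
  if (fraction <= 0 || fraction >= 1) stop("fraction must lie in (0, 1)")
  nTrain <- round(fraction * n)
  if (nTrain < 1L || nTrain >= n)
    stop("fraction leaves no test (or no train) record at n = ", n)
  idx <- .withSeed(seed, sample(n, nTrain))
  rec <- occ@records
  list(
    train = occurrenceSet(rec[sort(idx), , drop = FALSE], occ@provenance),
    test = occurrenceSet(rec[-sort(idx), , drop = FALSE], occ@provenance)
  )
}

#' Select the best subset of replicate models
#'
#' Best-subsets protocol: keep replicates whose training omission is at most
#' `omissionMax`; compute each survivor's commission (fraction of modelling
#' region cells predicted present); keep the `k` survivors whose commission is
#' closest to the survivor median (ties broken by lower omission, then by
#' replicate index).
#'
#' @param replicates list of [RuleSetModel-class].
#' @param regionEnv environment matrix of the modelling region's cells
#'   (commission is measured over it).
#' @param omissionMax omission filter (default 0.10).
#' @param k ensemble size (default 10).
#' @param consensus votes needed for binary presence (default majority,
#'   `ceiling(k / 2)`).
#' @return A [NicheEnsemble-class].
#' @export
selectBestSubset <- function(replicates, regionEnv, omissionMax = 0.10,
                             k = 10L, consensus = ceiling(k / 2)) {
  omission <- vapply(replicates, function(m) m@omission, 1.0)
  commission <- vapply(replicates, function(m) {
    if (is.na(m@commission))
      mean(.predictRules(m@rules, regionEnv[, m@variables, drop = FALSE]))
    else m@commission
  }, 1.0)
  pass <- omission <= omissionMax
  if (sum(pass) < k)
    stop("only ", sum(pass), " of ", length(replicates),
         " replicates pass the omission filter (need ", k, ")")
  med <- stats::median(commission[pass])
  cand <- which(pass)
  ord <- cand[order(abs(commission[cand] - med), omission[cand], cand)]
  chosen <- ord[seq_len(k)]
  members <- lapply(chosen, function(i) {
    m <- replicates[[i]]
    m@commission <- commission[i]
    m
  })
  log <- data.frame(replicate = seq_along(replicates), omission = omission,
                    commission = commission,
                    selected = seq_along(replicates) %in% chosen)
  new("NicheEnsemble", members = members, selectionLog = log,
      omissionMax = omissionMax, consensus = as.integer(consensus))
}

#' Modelling-region cells around a season's records
#'
#' The union of grid cells within a buffered bounding box of the records — the
#' extent over which backgrounds are sampled and commission is measured.
#'
#' @param grid a [GridSpec-class].
#' @param occ the season's [OccurrenceSet-class].
#' @param buffer bounding-box buffer in degrees (default 1).
#' @return two-column (row, col) integer matrix of region cells.
#' @export
regionCells <- function(grid, occ, buffer = 1) {
  rec <- occ@records
  lonR <- range(rec$lon) + c(-buffer, buffer)
  latR <- range(rec$lat) + c(-buffer, buffer)
  rows <- which(grid@yOrigin - (seq_len(grid@nRows) - 0.5) * grid@cellSize >= latR[1] &
                grid@yOrigin - (seq_len(grid@nRows) - 0.5) * grid@cellSize <= latR[2])
  cols <- which(grid@xOrigin + (seq_len(grid@nCols) - 0.5) * grid@cellSize >= lonR[1] &
                grid@xOrigin + (seq_len(grid@nCols) - 0.5) * grid@cellSize <= lonR[2])
  if (!length(rows) || !length(cols)) stop("empty modelling region")
  as.matrix(expand.grid(row = rows, col = cols))
}

#' Fit a season's replicate models and select the best subset
#'
#' Convenience wrapper running the full per-season protocol: extract training
#' climate, sample a background from the modelling region (default 10000 cells
#' or all region cells if fewer), fit `nReplicates` rule-set models with
#' derived seeds, and apply [selectBestSubset()].
#'
#' @param stack a [ClimateStack-class].
#' @param train training [OccurrenceSet-class] for the season.
#' @param months the season's months.
#' @param nReplicates replicates to fit (default 100).
#' @param k,omissionMax,consensus passed to [selectBestSubset()].
#' @param backgroundN background sample size (default 10000).
#' @param buffer modelling-region buffer, degrees.
#' @param params [gaParams()] settings.
#' @param seed integer seed (replicate seeds derived from it).
#' @return A [NicheEnsemble-class].
#' @export
fitSeasonEnsemble <- function(stack, train, months, nReplicates = 100L,
                              k = 10L, omissionMax = 0.10,
                              consensus = ceiling(k / 2),
                              backgroundN = 10000L, buffer = 1,
                              params = gaParams(), seed = 1L) {
  presence <- extractEnv(stack, train, months)
  region <- regionCells(stack@grid, train, buffer)
  regionEnv <- cellEnvMatrix(stack, months, region)
  bgN <- min(backgroundN, nrow(regionEnv))
  background <- .withSeed(deriveSeed(seed, "background"),
                          regionEnv[sample(nrow(regionEnv), bgN), , drop = FALSE])
  replicates <- lapply(seq_len(nReplicates), function(i) {
    fitRuleModel(presence, background, params,
                 seed = deriveSeed(seed, paste0("replicate_", i)))
  })
  selectBestSubset(replicates, regionEnv, omissionMax, k, consensus)
}

#' Predict / project an ensemble onto a month set
#'
#' Per cell, agreement is the number of ensemble members predicting presence on
#' the mean environment of `months`; the binary map applies the ensemble's
#' consensus threshold. Projecting onto a different season's months is the same
#' call (transferability). Nodata cells stay nodata. Deterministic: no RNG.
#'
#' @param ensemble a [NicheEnsemble-class].
#' @param stack a [ClimateStack-class].
#' @param months months to predict on.
#' @return A [SuitabilityMap-class].
#' @export
predictSuitability <- function(ensemble, stack, months) {
  grid <- stack@grid
  env <- cellEnvMatrix(stack, months)
  agree <- rep(0L, nrow(env))
  for (m in ensemble@members)
    agree <- agree + .predictRules(m@rules, env[, m@variables, drop = FALSE])
  rc <- do.call(rbind, strsplit(rownames(env), ":", fixed = TRUE))
  rc <- matrix(as.integer(rc), ncol = 2L)
  agreement <- matrix(NA_integer_, grid@nRows, grid@nCols)
  agreement[rc] <- agree
  new("SuitabilityMap", grid = grid, agreement = agreement,
      k = length(ensemble@members), consensus = ensemble@consensus)
}

#' Directional geographic overlap of two binary maps
#'
#' `overlap(a -> b) = 100 * |a AND b| / |a|` over cells that are nodata in
#' neither map. An empty map gives `NA` in its direction (reported, not an
#' error).
#'
#' @param mapA,mapB [SuitabilityMap-class] objects on the same grid.
#' @return named numeric: `a_to_b`, `b_to_a` (percentages).
#' @export
geographicOverlap <- function(mapA, mapB) {
  if (!identical(mapA@grid, mapB@grid)) stop("maps must share one grid")
  a <- binaryMap(mapA); b <- binaryMap(mapB)
  ok <- !is.na(a) & !is.na(b)
  a <- a & ok; b <- b & ok
  inter <- sum(a & b)
  c(a_to_b = if (sum(a) == 0L) NA_real_ else 100 * inter / sum(a),
    b_to_a = if (sum(b) == 0L) NA_real_ else 100 * inter / sum(b))
}
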