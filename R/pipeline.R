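# End-to-end seasonal analysis from one configuration object, plus monthly
# climate profiles and the report tables.

#' Pipeline configuration
#'
#' Assembles every tunable of the full seasonal analysis in one place; all
#' downstream stages read their settings from here and stage seeds are derived
#' from the one global seed, so a config determines a run bit-for-bit.
#'
#' Inputs are either a synthetic scenario (`scenario$kind`, `scenario$delta`)
#' or files (`paths$rasterDir` of ESRI ASCII grids plus `paths$occurrences`
#' CSV).
#'
#' @param seed global integer seed.
#' @param scenario list: `kind` ("follower"/"switcher"/"custom"), `delta`,
#'   plus any further [makeScenario()] argument (`grid`, `counts`, `params`,
#'   `spread`). Ignored when `paths` is given.
#' @param paths optional list: `rasterDir`, `occurrences`.
#' @param seasonMap month-to-season map (default [defaultSeasonMap()]).
#' @param model list: `nReplicates` (100), `k` (10), `omissionMax` (0.10),
#'   `consensus` (majority), `backgroundN` (10000), `buffer` (1 degree),
#'   `trainFraction` (0.8), `ga` ([gaParams()] overrides).
#' @param evaluation list: `E` (0.05), `nBoot` (1000), `bootFraction` (0.5).
#' @param structure list: `cutoffs` ([defaultZoneCutoffs()] or "auto").
#' @param breadth list: `latticeN` (100), `alpha` (NULL = data-driven),
#'   `maxPoints` (1500; larger clouds are deterministically thinned before
#'   triangulation).
#' @param similarity list: `R` (100), `nReps` (100), `bandwidth` (NULL).
#' @return a `runConfig` list.
#' @export
runConfig <- function(seed = 1L,
                      scenario = list(kind = "switcher", delta = 6),
                      paths = NULL,
                      seasonMap = defaultSeasonMap(),
                      model = list(), evaluation = list(),
                      structure = list(), breadth = list(),
                      similarity = list()) {
  cfg <- list(
    seed = as.integer(seed), scenario = scenario, paths = paths,
    seasonMap = seasonMap,
    model = utils::modifyList(list(
      nReplicates = 100L, k = 10L, omissionMax = 0.10, consensus = NULL,
      backgroundN = 10000L, buffer = 1, trainFraction = 0.8, ga = list()
    ), model),
    evaluation = utils::modifyList(list(
      E = 0.05, nBoot = 1000L, bootFraction = 0.5
    ), evaluation),
    structure = utils::modifyList(list(cutoffs = defaultZoneCutoffs()), structure),
    breadth = utils::modifyList(list(latticeN = 100L, alpha = NULL,
                                     maxPoints = 1500L), breadth),
    similarity = utils::modifyList(list(R = 100L, nReps = 100L,
                                        bandwidth = NULL), similarity)
  )
  class(cfg) <- c("runConfig", "list")
  cfg
}

#' Five-number climate profile
#'
#' Per-variable min, lower quartile, median, upper quartile and max of the
#' climate at a set of records or cells over `months` — comparable across
#' sources (month records vs season models vs projections).
#'
#' @param stack a [ClimateStack-class].
#' @param months months to average over.
#' @param occ an [OccurrenceSet-class] selector, or
#' @param cells a two-column (row, col) cell selector (one of the two).
#' @return data.frame: variable, min, q1, median, q3, max.
#' @export
climateProfile <- function(stack, months, occ = NULL, cells = NULL) {
  env <- if (!is.null(occ)) extractEnv(stack, occ, months)
         else if (!is.null(cells)) cellEnvMatrix(stack, months, cells)
         else stop("supply occ or cells")
  if (!nrow(env)) stop("empty selection")
  q <- apply(env, 2L, stats::quantile, probs = c(0, 0.25, 0.5, 0.75, 1),
             names = FALSE)
  data.frame(variable = colnames(env), min = q[1L, ], q1 = q[2L, ],
             median = q[3L, ], q3 = q[4L, ], max = q[5L, ],
             row.names = NULL, stringsAsFactors = FALSE)
}

# deterministic thinning of large point clouds before triangulation
.thinCloud <- function(cloud, maxPoints) {
  n <- nrow(cloud@points)
  if (n <= maxPoints) return(cloud)
  keep <- round(seq(1L, n, length.out = maxPoints))
  new("PolarCloud", points = cloud@points[keep, , drop = FALSE],
      angles = cloud@angles, scaling = cloud@scaling)
}

.seasonMonths <- function(seasonMap, season) {
  as.integer(names(seasonMap)[seasonMap == season])
}

# cells predicted present by a map, as a (row, col) matrix
.presenceCells <- function(map) which(binaryMap(map), arr.ind = TRUE)

#' Run the full seasonal niche analysis
#'
#' Executes the whole workflow: season assignment and dedup; per-season
#' calibration split, replicate fitting and best-subsets selection; partial
#' ROC evaluation; inter-prediction between seasons and projection onto each
#' migratory month with directional polar-MCP overlaps (the report table);
#' niche structure with migratory-record zone classification; polar breadth
#' and its between-season overlap; the PCA-env similarity test in both
#' directions; and monthly climate profiles. Fully reproducible under
#' `config$seed`; rerunning a config yields a bit-identical summary.
#'
#' @param config a [runConfig()].
#' @param outDir optional directory; when given, `summary.json`, the overlap
#'   table and record zone assignments are written there.
#' @return list with `summary` (plain, JSON-ready) and the fitted objects
#'   (`stack`, `occurrences`, `ensembles`, `maps`, `structures`, `breadth`,
#'   `similarity`).
#' @export
runPipeline <- function(config = runConfig(), outDir = NULL) {
  seed <- config$seed
  stage <- function(name) deriveSeed(seed, name)

  # ---- inputs ----
  if (!is.null(config$paths)) {
    stack <- readClimateStack(config$paths$rasterDir)
    occ <- readOccurrences(config$paths$occurrences)
  } else {
    scArgs <- config$scenario
    scArgs$kind <- NULL
    if (is.null(scArgs$delta) && config$scenario$kind != "switcher") scArgs$delta <- 0
    sc <- do.call(makeScenario, c(list(kind = config$scenario$kind,
                                       seed = stage("scenario")), scArgs))
    stack <- sc@stack
    occ <- sampleScenario(sc)
  }
  if (!"season" %in% names(occ@records))
    occ <- assignSeason(occ, config$seasonMap)
  occ <- dedupOccurrences(occ, stack@grid)
  rec <- occ@records

  mCfg <- config$model
  ga <- do.call(gaParams, mCfg$ga)
  k <- mCfg$k
  consensus <- if (is.null(mCfg$consensus)) ceiling(k / 2) else mCfg$consensus
  seasons <- c("breeding", "winter")
  months <- lapply(stats::setNames(seasons, seasons),
                   function(s) .seasonMonths(config$seasonMap, s))
  migMonths <- .seasonMonths(config$seasonMap, "migratory")

  # ---- per-season fit + evaluation ----
  ensembles <- list(); maps <- list(); proc <- list(); splits <- list()
  for (s in seasons) {
    sOcc <- occurrenceSet(rec[rec$season == s, , drop = FALSE], occ@provenance)
    splits[[s]] <- splitCalibration(sOcc, mCfg$trainFraction,
                                    seed = stage(paste0("split_", s)))
    ensembles[[s]] <- fitSeasonEnsemble(
      stack, splits[[s]]$train, months[[s]],
      nReplicates = mCfg$nReplicates, k = k, omissionMax = mCfg$omissionMax,
      consensus = consensus, backgroundN = mCfg$backgroundN,
      buffer = mCfg$buffer, params = ga, seed = stage(paste0("fit_", s)))
    maps[[s]] <- predictSuitability(ensembles[[s]], stack, months[[s]])
    proc[[s]] <- partialROC(maps[[s]], splits[[s]]$test,
                            E = config$evaluation$E,
                            nBoot = config$evaluation$nBoot,
                            bootFraction = config$evaluation$bootFraction,
                            seed = stage(paste0("proc_", s)))
  }

  # ---- inter-prediction and migratory projections ----
  cross <- list(
    breeding_to_winter = predictSuitability(ensembles$breeding, stack, months$winter),
    winter_to_breeding = predictSuitability(ensembles$winter, stack, months$breeding)
  )
  interPrediction <- list(
    breeding_to_winter = as.list(geographicOverlap(cross$breeding_to_winter, maps$winter)),
    winter_to_breeding = as.list(geographicOverlap(cross$winter_to_breeding, maps$breeding))
  )
  projections <- list()
  for (s in seasons) for (m in migMonths)
    projections[[sprintf("%s_m%02d", s, m)]] <-
      predictSuitability(ensembles[[s]], stack, m)

  # ---- polar breadth (shared scaling across every compared stage) ----
  bCfg <- config$breadth
  seasonEnv <- lapply(stats::setNames(seasons, seasons), function(s)
    cellEnvMatrix(stack, months[[s]], .presenceCells(maps[[s]])))
  projEnv <- lapply(stats::setNames(names(projections), names(projections)),
                    function(nm) {
    m <- as.integer(sub(".*_m", "", nm))
    cells <- .presenceCells(projections[[nm]])
    if (nrow(cells)) cellEnvMatrix(stack, m, cells) else NULL
  })
  scaling <- polarScaling(c(seasonEnv, Filter(Negate(is.null), projEnv)))
  hullOf <- function(env) {
    cloud <- .thinCloud(polarCoordinates(env, scaling = scaling), bCfg$maxPoints)
    alphaHull(cloud, alpha = bCfg$alpha)
  }
  hulls <- lapply(seasonEnv, hullOf)
  seasonBreadth <- breadthOverlap(hulls$breeding, hulls$winter, n = bCfg$latticeN)

  overlapTable <- do.call(rbind, lapply(seasons, function(s) {
    do.call(rbind, lapply(migMonths, function(m) {
      env <- projEnv[[sprintf("%s_m%02d", s, m)]]
      if (is.null(env) || nrow(env) < 3L)  # no predicted area: report NA
        return(data.frame(season = s, month = m, season_to_month = NA_real_,
                          month_to_season = NA_real_, pixels_month = NA_real_))
      ov <- breadthOverlap(hulls[[s]], hullOf(env), n = bCfg$latticeN)
      data.frame(season = s, month = m, season_to_month = ov$a_to_b,
                 month_to_season = ov$b_to_a, pixels_month = ov$pixelsB)
    }))
  }))

  # ---- niche structure and migratory record placement ----
  structures <- lapply(stats::setNames(seasons, seasons), function(s)
    buildNicheStructure(maps[[s]], stack, months[[s]],
                        cutoffs = config$structure$cutoffs))
  migOcc <- occurrenceSet(rec[rec$season == "migratory", , drop = FALSE])
  zones <- lapply(structures, function(st) classifyRecords(migOcc, st, stack))

  # ---- PCA-env similarity, both directions ----
  # availability background per season: the climate of its modelling region
  # (the same extent models were calibrated over), not just the predicted
  # cells -- the occurrence/availability ratio is unstable when the
  # availability surface is as concentrated as the occurrences themselves
  simCfg <- config$similarity
  regionEnv <- lapply(stats::setNames(seasons, seasons), function(s) {
    sOcc <- occurrenceSet(rec[rec$season == s, , drop = FALSE])
    cellEnvMatrix(stack, months[[s]],
                  regionCells(stack@grid, sOcc, mCfg$buffer))
  })
  space <- buildPcaEnv(regionEnv$breeding, regionEnv$winter, R = simCfg$R)
  occEnv <- lapply(stats::setNames(seasons, seasons), function(s)
    extractEnv(stack, occurrenceSet(rec[rec$season == s, , drop = FALSE]),
               months[[s]]))
  similarity <- list(
    breeding_vs_winter = similarityTest(
      occEnv$breeding, occEnv$winter, regionEnv$breeding, regionEnv$winter,
      space, nReps = simCfg$nReps, direction = "a_vs_b",
      bandwidth = simCfg$bandwidth, seed = stage("sim_ab")),
    winter_vs_breeding = similarityTest(
      occEnv$breeding, occEnv$winter, regionEnv$breeding, regionEnv$winter,
      space, nReps = simCfg$nReps, direction = "b_vs_a",
      bandwidth = simCfg$bandwidth, seed = stage("sim_ba"))
  )

  # ---- climate profiles of the migratory record months ----
  profiles <- lapply(stats::setNames(migMonths, sprintf("m%02d", migMonths)),
                     function(m) {
    sub <- occurrenceSet(rec[rec$month == m, , drop = FALSE])
    if (!length(sub)) return(NULL)
    climateProfile(stack, m, occ = sub)
  })

  # ---- summary: every number traceable to one module output above ----
  summary <- list(
    config = list(seed = seed,
                  scenario = if (is.null(config$paths))
                    config$scenario[intersect(c("kind", "delta"),
                                              names(config$scenario))]
                  else NULL,
                  nReplicates = mCfg$nReplicates, k = k,
                  omissionMax = mCfg$omissionMax, consensus = consensus,
                  E = config$evaluation$E, cutoffs = config$structure$cutoffs),
    records = as.list(table(rec$season)),
    seasons = lapply(stats::setNames(seasons, seasons), function(s) list(
      nTrain = length(splits[[s]]$train), nTest = length(splits[[s]]$test),
      presenceCells = sum(binaryMap(maps[[s]]), na.rm = TRUE),
      aucRatio = aucRatio(proc[[s]]), pRocP = pValue(proc[[s]]))),
    interPrediction = interPrediction,
    overlapTable = overlapTable,
    breadth = list(pixelsBreeding = seasonBreadth$pixelsA,
                   pixelsWinter = seasonBreadth$pixelsB,
                   breeding_to_winter = seasonBreadth$a_to_b,
                   winter_to_breeding = seasonBreadth$b_to_a,
                   areaBreeding = breadthArea(hulls$breeding),
                   areaWinter = breadthArea(hulls$winter)),
    migratoryZones = lapply(zones, function(z) as.list(z$counts)),
    similarity = lapply(similarity, function(r)
      list(dObserved = dObserved(r), pValue = pValue(r))),
    profiles = Filter(Negate(is.null), profiles)
  )

  if (!is.null(outDir)) {
    dir.create(outDir, showWarnings = FALSE, recursive = TRUE)
    jsonlite::write_json(summary, file.path(outDir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
    utils::write.csv(overlapTable, file.path(outDir, "overlap_table.csv"),
                     row.names = FALSE)
    utils::write.csv(zones$winter$assignments,
                     file.path(outDir, "migratory_zones_winter.csv"),
                     row.names = FALSE)
  }
  list(summary = summary, stack = stack, occurrences = occ,
       ensembles = ensembles, maps = maps, partialROC = proc,
       projections = projections, structures = structures,
       hulls = hulls, similarity = similarity)
}

#' Read a pipeline configuration from YAML or JSON
#'
#' Scalars and nested sections map onto [runConfig()] arguments; anything not
#' present keeps its default. A `scenario: {kind: switcher, delta: 6}` section
#' is enough for a synthetic run; a `paths:` section points at rasters and an
#' occurrence CSV instead.
#'
#' @param path a `.yaml`/`.yml` or `.json` file.
#' @return a `runConfig` list.
#' @export
readRunConfig <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE))
    jsonlite::read_json(path, simplifyVector = TRUE)
  else yaml::read_yaml(path)
  known <- setdiff(names(formals(runConfig)), "...")
  unknown <- setdiff(names(raw), known)
  if (length(unknown))
    stop("unknown config field(s): ", paste(unknown, collapse = ", "))
  do.call(runConfig, raw)
}
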