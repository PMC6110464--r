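# Synthetic climate stacks and season-labelled occurrences with known
# ground-truth niche structure, so every pipeline stage is testable without
# external data.

#' Ground-truth niche specification
#'
#' A diagonal Gaussian niche in climate space: suitability of a cell is
#' `exp(-0.5 * sum(((x - centroid) / spread)^2))` on the mean climate of the
#' spec's months.
#'
#' @slot centroid named climate vector (`tmax`, `tmin`, `prec`).
#' @slot spread per-variable standard deviations (same names).
#' @slot season season label.
#' @slot months months this niche is occupied.
#' @slot nRecords number of records to draw.
#' @export
setClass("NicheSpec",
  representation(centroid = "numeric", spread = "numeric", season = "character",
                 months = "integer", nRecords = "integer")
)

setValidity("NicheSpec", function(object) {
  msg <- character()
  if (any(object@spread <= 0)) msg <- c(msg, "spreads must be > 0")
  if (object@nRecords < 1L) msg <- c(msg, "nRecords must be >= 1")
  if (!identical(names(object@centroid), .CLIMATE_VARIABLES) ||
      !identical(names(object@spread), .CLIMATE_VARIABLES))
    msg <- c(msg, "centroid and spread must be named tmax, tmin, prec")
  if (length(msg)) msg else TRUE
})

#' @rdname NicheSpec-class
#' @param centroid,spread,season,months,nRecords see slots.
#' @return A [NicheSpec-class].
#' @export
nicheSpec <- function(centroid, spread, season, months, nRecords) {
  new("NicheSpec",
    centroid = centroid[.CLIMATE_VARIABLES], spread = spread[.CLIMATE_VARIABLES],
    season = season, months = as.integer(months), nRecords = as.integer(nRecords))
}

setMethod("show", "NicheSpec", function(object) {
  cat(sprintf("NicheSpec %s (months %s): %d records, centroid (%s)\n",
    object@season, paste(object@months, collapse = ","), object@nRecords,
    paste(sprintf("%s %.1f", names(object@centroid), object@centroid), collapse = ", ")))
})

#' A full synthetic study scenario
#'
#' A 12-month climate stack plus the ground-truth niches of every stage of the
#' annual cycle, reproducible under `seed`.
#'
#' @slot stack the [ClimateStack-class] (12 months).
#' @slot niches list of [NicheSpec-class], one per stage (migratory months get
#'   one spec each).
#' @slot seed integer seed.
#' @slot kind `"follower"`, `"switcher"` or `"custom"`.
#' @slot delta centroid separation in standardized (spread) units.
#' @export
setClass("Scenario",
  representation(stack = "ClimateStack", niches = "list", seed = "integer",
                 kind = "character", delta = "numeric")
)

setMethod("show", "Scenario", function(object) {
  cat(sprintf("Scenario '%s' (delta = %g, seed %d): %d niches on a %d x %d grid\n",
    object@kind, object@delta, object@seed, length(object@niches),
    object@stack@grid@nRows, object@stack@grid@nCols))
})

#' Default climate-surface parameters
#'
#' Monthly surfaces emulating interpolated climatologies: a linear latitudinal
#' gradient, a sinusoidal seasonal cycle peaking in July for temperature (and
#' in August for precipitation, whose cycle is phase-shifted and has its own
#' gradient), and a smooth month-invariant spatial noise field per variable.
#'
#' Units: temperatures in degrees C, precipitation in mm. `tmaxRowGradient` is
#' degrees C per grid row (row 1 is northernmost, so a positive value warms
#' southwards).
#'
#' @param tmaxBase tmax at a fictitious row 0 in January-July average terms.
#' @param tmaxRowGradient warming per row southwards.
#' @param seasonalAmplitude half the July-January tmax difference.
#' @param diurnalOffset mean tmax minus tmin.
#' @param diurnalNoise amplitude of the smooth spatial variation of the
#'   diurnal range (so tmin is not a rigid copy of tmax, as in real
#'   climatologies where the daily range varies with aridity and terrain).
#' @param tmaxNoise sd-like amplitude of the smooth spatial noise on tmax/tmin.
#' @param precBase,precColGradient,precAmplitude,precPhase,precNoise the
#'   precipitation surface: base, per-*column* gradient (drying eastwards for
#'   negative values, so moisture varies along an axis independent of
#'   temperature), seasonal amplitude, peak month and noise amplitude.
#' @return a named list of parameters for [makeClimateStack()].
#' @export
climateParams <- function(tmaxBase = 8, tmaxRowGradient = 0.25,
                          seasonalAmplitude = 12, diurnalOffset = 10,
                          diurnalNoise = 1, tmaxNoise = 0.8,
                          precBase = 70, precColGradient = -0.3,
                          precAmplitude = 25, precPhase = 8, precNoise = 5) {
  list(tmaxBase = tmaxBase, tmaxRowGradient = tmaxRowGradient,
       seasonalAmplitude = seasonalAmplitude, diurnalOffset = diurnalOffset,
       diurnalNoise = diurnalNoise, tmaxNoise = tmaxNoise, precBase = precBase,
       precColGradient = precColGradient, precAmplitude = precAmplitude,
       precPhase = precPhase, precNoise = precNoise)
}

# Smooth spatial noise: coarse iid normal field, bilinearly interpolated to the
# full grid. Month-invariant so monthly differences at a fixed cell follow the
# seasonal cycle exactly.
.smoothNoise <- function(nr, nc, amplitude, coarse = 8L) {
  if (amplitude == 0) return(matrix(0, nr, nc))
  cr <- max(2L, coarse); cc <- max(2L, coarse)
  field <- matrix(stats::rnorm(cr * cc), cr, cc)
  ri <- seq(1, cr, length.out = nr)
  ci <- seq(1, cc, length.out = nc)
  r0 <- pmin(floor(ri), cr - 1L); rt <- ri - r0
  c0 <- pmin(floor(ci), cc - 1L); ct <- ci - c0
  top <- field[r0, c0] * outer(1 - rt, 1 - ct) + field[r0, c0 + 1L] * outer(1 - rt, ct)
  bot <- field[r0 + 1L, c0] * outer(rt, 1 - ct) + field[r0 + 1L, c0 + 1L] * outer(rt, ct)
  amplitude * (top + bot)
}

#' Generate a synthetic monthly climate stack
#'
#' Builds 12 months of `tmax`, `tmin` and `prec` on `grid`:
#' `tmax(m) = base + rowGradient * row + amplitude * cos(2 * pi * (m - 7) / 12) + noise`,
#' `tmin = tmax - diurnalOffset + diurnal-range noise`, and an analogous
#' precipitation surface with its own (longitudinal) gradient, amplitude and
#' phase, clipped at zero (clipped cells are reported). The same seed yields a
#' bit-identical stack.
#'
#' @param grid a [GridSpec-class].
#' @param params from [climateParams()].
#' @param seed integer seed for the noise fields.
#' @param months months to generate (default all 12).
#' @return A [ClimateStack-class].
#' @export
makeClimateStack <- function(grid, params = climateParams(), seed = 1L,
                             months = 1:12) {
  nr <- grid@nRows; nc <- grid@nCols
  .withSeed(seed, {
    noiseT <- .smoothNoise(nr, nc, params$tmaxNoise)
    noiseD <- .smoothNoise(nr, nc, params$diurnalNoise)
    noiseP <- .smoothNoise(nr, nc, params$precNoise)
  })
  rowField <- matrix(seq_len(nr), nr, nc)
  colField <- matrix(seq_len(nc), nr, nc, byrow = TRUE)
  layers <- list()
  nClipped <- 0L
  for (m in months) {
    cycT <- params$seasonalAmplitude * cos(2 * pi * (m - 7) / 12)
    tmax <- params$tmaxBase + params$tmaxRowGradient * rowField + cycT + noiseT
    cycP <- params$precAmplitude * cos(2 * pi * (m - params$precPhase) / 12)
    prec <- params$precBase + params$precColGradient * colField + cycP + noiseP
    nClipped <- nClipped + sum(prec < 0)
    prec[prec < 0] <- 0
    layers[[.layerKey("tmax", m)]] <- climateLayer(grid, "tmax", m, tmax)
    layers[[.layerKey("tmin", m)]] <-
      climateLayer(grid, "tmin", m, tmax - params$diurnalOffset + noiseD)
    layers[[.layerKey("prec", m)]] <- climateLayer(grid, "prec", m, prec)
  }
  if (nClipped > 0)
    message("makeClimateStack: clipped ", nClipped, " negative precipitation cell(s) at 0")
  climateStack(layers)
}

# Gaussian suitability of each row of an env matrix under a NicheSpec,
# normalized so the most suitable cell has s = 1 (keeps far cells above
# underflow where possible).
.suitability <- function(env, spec) {
  z <- sweep(sweep(env, 2L, spec@centroid[colnames(env)]), 2L,
             spec@spread[colnames(env)], "/")
  logs <- -0.5 * rowSums(z^2)
  exp(logs - max(logs))
}

#' Sample occurrences from a ground-truth niche
#'
#' Cells are drawn without replacement with probability proportional to the
#' Gaussian suitability of their mean climate over `months` (so generated data
#' is already spatially unique); each drawn cell yields one record at the cell
#' centre with a month drawn uniformly from `months`. Same seed, same output.
#'
#' @param stack a [ClimateStack-class].
#' @param spec a [NicheSpec-class].
#' @param months months the records may carry (default: the spec's months).
#' @param seed integer seed.
#' @return An [OccurrenceSet-class] with `season` set from the spec.
#' @export
sampleOccurrences <- function(stack, spec, months = spec@months, seed = 1L) {
  stopifnot(length(months) >= 1L)
  env <- cellEnvMatrix(stack, months)
  s <- .suitability(env, spec)
  ok <- which(s > 0)
  if (length(ok) < spec@nRecords)
    stop("only ", length(ok), " cells with positive suitability for ",
         spec@nRecords, " records")
  .withSeed(seed, {
    pick <- sample(ok, spec@nRecords, replace = FALSE, prob = s[ok])
    recMonth <- if (length(months) == 1L) rep(months, spec@nRecords)
                else sample(months, spec@nRecords, replace = TRUE)
  })
  rc <- do.call(rbind, strsplit(rownames(env)[pick], ":", fixed = TRUE))
  rc <- matrix(as.integer(rc), ncol = 2L)
  xy <- .xyFromCell(stack@grid, rc[, 1L], rc[, 2L])
  occurrenceSet(data.frame(
    id = sprintf("%s_m%02d_%04d", spec@season, recMonth, seq_len(spec@nRecords)),
    lon = xy[, "lon"], lat = xy[, "lat"],
    month = recMonth, season = spec@season,
    stringsAsFactors = FALSE
  ), provenance = sprintf("synthetic %s niche", spec@season))
}

#' Build a follower / switcher study scenario
#'
#' Constructs a 12-month stack on a 120 x 120 grid and the stage niches of a
#' migratory annual cycle. A *follower* occupies one climate centroid in both
#' breeding and winter; a *switcher*'s seasonal centroids are `delta`
#' standardized (spread) units apart, placed symmetrically about the climate
#' shared by both seasons along the axis separating winter-typical from
#' breeding-typical climate. Migratory-month niches sit at the midpoint —
#' between the two seasonal niches.
#'
#' Default record counts are 246 breeding, 83 winter, and 28/20/33/15 for
#' April/September/October/November.
#'
#' @param kind `"follower"` (delta forced to 0), `"switcher"` or `"custom"`.
#' @param seed integer seed (stage seeds are derived from it).
#' @param delta centroid separation in standardized units (switcher default 6).
#' @param grid the shared [GridSpec-class].
#' @param params climate parameters ([climateParams()]).
#' @param spread per-variable niche spreads (climate units).
#' @param counts named record counts: `breeding`, `winter`, `m04`, `m09`,
#'   `m10`, `m11`.
#' @return A [Scenario-class].
#' @export
makeScenario <- function(kind = c("follower", "switcher", "custom"), seed = 1L,
                         delta = if (kind == "switcher") 6 else 0,
                         grid = GridSpec(120, 120, xOrigin = -106, yOrigin = 50,
                                         cellSize = 0.0416),
                         params = climateParams(),
                         spread = c(tmax = 1.5, tmin = 1.5, prec = 5),
                         counts = c(breeding = 246, winter = 83,
                                    m04 = 28, m09 = 20, m10 = 33, m11 = 15)) {
  kind <- match.arg(kind)
  if (kind == "follower") delta <- 0
  stack <- makeClimateStack(grid, params, seed = deriveSeed(seed, "climate"))
  spread <- spread[.CLIMATE_VARIABLES]

  seasonMonths <- list(breeding = c(5L, 6L), winter = c(12L, 1L, 2L))
  envB <- cellEnvMatrix(stack, seasonMonths$breeding)
  envW <- cellEnvMatrix(stack, seasonMonths$winter)

  # climate shared by both seasons: per-variable midpoint of the overlap of
  # the two seasons' realized ranges (interior to both, so records drawn
  # around it are not truncated by a range edge); this is the follower
  # centroid
  lo <- pmax(apply(envB, 2L, min), apply(envW, 2L, min))
  hi <- pmin(apply(envB, 2L, max), apply(envW, 2L, max))
  if (any(lo >= hi))
    stop("no climate shared between seasons; widen the latitudinal gradient")
  shared <- (lo + hi) / 2

  # unit direction (standardized) from breeding-typical toward winter-typical
  u <- (colMeans(envW) - colMeans(envB)) / spread
  u <- u / sqrt(sum(u^2))
  cWinter <- shared + (delta / 2) * u * spread
  cBreeding <- shared - (delta / 2) * u * spread

  .assertRealized <- function(centroid, env, label) {
    lo <- apply(env, 2L, min); hi <- apply(env, 2L, max)
    slack <- 2 * spread
    if (any(centroid < lo - slack | centroid > hi + slack))
      stop("the ", label, " centroid lies outside the climate realized in its season")
  }
  .assertRealized(cBreeding, envB, "breeding")
  .assertRealized(cWinter, envW, "winter")

  niches <- list(
    nicheSpec(cBreeding, spread, "breeding", seasonMonths$breeding, counts[["breeding"]]),
    nicheSpec(cWinter, spread, "winter", seasonMonths$winter, counts[["winter"]])
  )
  for (m in c(4L, 9L, 10L, 11L)) {
    niches <- c(niches, nicheSpec(shared, spread, "migratory", m,
                                  counts[[sprintf("m%02d", m)]]))
  }
  names(niches) <- c("breeding", "winter", sprintf("m%02d", c(4L, 9L, 10L, 11L)))
  new("Scenario", stack = stack, niches = niches, seed = as.integer(seed),
      kind = kind, delta = as.numeric(delta))
}

#' Draw the full occurrence set of a scenario
#'
#' Samples every stage niche (breeding, winter, each migratory month) with
#' stage seeds derived from the scenario seed and concatenates the records.
#'
#' @param scenario a [Scenario-class].
#' @return An [OccurrenceSet-class] with seasons labelled.
#' @export
sampleScenario <- function(scenario) {
  sets <- lapply(names(scenario@niches), function(nm) {
    sp <- scenario@niches[[nm]]
    sampleOccurrences(scenario@stack, sp,
                      seed = deriveSeed(scenario@seed, paste0("occ_", nm)))
  })
  rec <- do.call(rbind, lapply(sets, occurrenceRecords))
  occurrenceSet(rec, provenance = sprintf("synthetic scenario '%s' seed %d",
                                          scenario@kind, scenario@seed))
}
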