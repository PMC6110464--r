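# Raster and occurrence I/O, record cleaning, and point extraction.
#
# The interchange raster format is the ESRI ASCII grid (one band per file,
# plain text): header lines ncols/nrows/xllcorner/yllcorner/cellsize/
# NODATA_value followed by rows of values from north to south. Filenames carry
# variable and month, e.g. tmax_05.asc (pattern configurable).

.ASCII_HEADER_KEYS <- c("ncols", "nrows", "xllcorner", "yllcorner",
                        "cellsize", "nodata_value")

#' Read an ESRI ASCII grid raster
#'
#' Reads a single-band ESRI ASCII grid into a [ClimateLayer-class]. Grid
#' metadata (origin, cell size, nodata sentinel) is preserved exactly; nodata
#' cells become `NA`.
#'
#' @param path path to the `.asc` file.
#' @param variable,month variable name and calendar month of the layer; if
#'   `NULL`, parsed from the filename (`<variable>_<mm>.asc`).
#' @return A [ClimateLayer-class].
#' @seealso [writeAsciiGrid()] for the inverse; round-trips are exact.
#' @export
readAsciiGrid <- function(path, variable = NULL, month = NULL) {
  if (!file.exists(path)) stop("unreadable file: ", path)
  lines <- readLines(path, warn = FALSE)
  hdr <- list()
  i <- 1L
  while (i <= length(lines)) {
    parts <- strsplit(trimws(lines[i]), "\\s+")[[1]]
    key <- tolower(parts[1])
    if (!key %in% .ASCII_HEADER_KEYS) break
    hdr[[key]] <- as.numeric(parts[2])
    i <- i + 1L
  }
  for (key in c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize")) {
    if (is.null(hdr[[key]]) || is.na(hdr[[key]]))
      stop("missing georeferencing field in ", path, ": ", key)
  }
  if (is.null(hdr$nodata_value)) hdr$nodata_value <- -9999
  vals <- scan(text = paste(lines[i:length(lines)], collapse = "\n"),
               what = double(), quiet = TRUE)
  nr <- as.integer(hdr$nrows); nc <- as.integer(hdr$ncols)
  if (length(vals) != nr * nc)
    stop("value count ", length(vals), " does not match ", nr, " x ", nc, " grid in ", path)
  values <- matrix(vals, nrow = nr, ncol = nc, byrow = TRUE)  # rows north->south
  values[values == hdr$nodata_value] <- NA_real_
  grid <- GridSpec(nr, nc,
    xOrigin = hdr$xllcorner,
    yOrigin = hdr$yllcorner + nr * hdr$cellsize,
    cellSize = hdr$cellsize, nodata = hdr$nodata_value)
  if (is.null(variable) || is.null(month)) {
    m <- regmatches(basename(path),
                    regexec("^([a-z]+)_([0-9]{2})\\.", basename(path)))[[1]]
    if (length(m) != 3L)
      stop("cannot parse variable/month from filename ", basename(path),
           "; pass them explicitly")
    variable <- m[2]
    month <- as.integer(m[3])
  }
  climateLayer(grid, variable, month, values)
}

#' Write an ESRI ASCII grid raster
#'
#' Writes a [ClimateLayer-class] so that [readAsciiGrid()] recovers the values
#' grid, nodata mask and [GridSpec-class] exactly (values are printed with full
#' double precision).
#'
#' @param layer a [ClimateLayer-class].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
writeAsciiGrid <- function(layer, path) {
  grid <- layer@grid
  vals <- layer@values
  vals[is.na(vals)] <- grid@nodata
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c(
    sprintf("ncols %d", grid@nCols),
    sprintf("nrows %d", grid@nRows),
    sprintf("xllcorner %.17g", grid@xOrigin),
    sprintf("yllcorner %.17g", grid@yOrigin - grid@nRows * grid@cellSize),
    sprintf("cellsize %.17g", grid@cellSize),
    sprintf("NODATA_value %.17g", grid@nodata)
  ), con)
  writeLines(apply(vals, 1L, function(r) paste(sprintf("%.17g", r), collapse = " ")), con)
  invisible(path)
}

#' Read or write a full climate stack directory
#'
#' One ASCII grid per (variable, month); filenames follow `pattern`.
#'
#' @param dir directory of `.asc` files.
#' @param months months to load (default: every month found for all three
#'   variables).
#' @param pattern `sprintf` pattern taking variable then month.
#' @return `readClimateStack`: a [ClimateStack-class]; `writeClimateStack`:
#'   `dir`, invisibly.
#' @export
readClimateStack <- function(dir, months = NULL, pattern = "%s_%02d.asc") {
  if (is.null(months)) {
    months <- Filter(function(m) {
      all(file.exists(file.path(dir, sprintf(pattern, .CLIMATE_VARIABLES, m))))
    }, 1:12)
    if (!length(months)) stop("no complete (tmax, tmin, prec) month found in ", dir)
  }
  layers <- list()
  for (m in months) for (v in .CLIMATE_VARIABLES) {
    layers[[.layerKey(v, m)]] <-
      readAsciiGrid(file.path(dir, sprintf(pattern, v, m)), variable = v, month = m)
  }
  climateStack(layers)
}

#' @rdname readClimateStack
#' @param stack a [ClimateStack-class] to write.
#' @export
writeClimateStack <- function(stack, dir, pattern = "%s_%02d.asc") {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  for (ly in stack@layers)
    writeAsciiGrid(ly, file.path(dir, sprintf(pattern, ly@variable, ly@month)))
  invisible(dir)
}

#' Read occurrence records from CSV
#'
#' Requires columns `id`, `lon`, `lat` and one of `month` or `date`
#' (ISO-8601; the month is taken from the date). An optional `season` column
#' is kept and overrides [assignSeason()].
#'
#' @param path CSV path.
#' @param provenance free text recorded on the set (default: the path).
#' @return An [OccurrenceSet-class].
#' @export
readOccurrences <- function(path, provenance = path) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE)
  need <- c("id", "lon", "lat")
  if (!all(need %in% names(df)))
    stop("occurrence CSV must have columns ", paste(need, collapse = ", "))
  if (!"month" %in% names(df)) {
    if (!"date" %in% names(df))
      stop("occurrence CSV must have a month or an ISO-8601 date column")
    df$month <- as.integer(format(as.Date(df$date), "%m"))
  }
  keep <- c("id", "lon", "lat", "month", intersect("season", names(df)))
  occurrenceSet(df[keep], provenance = provenance)
}

#' @rdname readOccurrences
#' @param occ an [OccurrenceSet-class] to write.
#' @export
writeOccurrences <- function(occ, path) {
  utils::write.csv(occ@records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Default month-to-season map
#'
#' Modelling seasons for a temperate grassland migrant: breeding May-June,
#' winter December-February, migratory April and September-November; the
#' transitional months March and August are excluded because records cannot be
#' assigned to a period with confidence.
#'
#' @return named character vector of length 12 (names `"1"`..`"12"`).
#' @export
defaultSeasonMap <- function() {
  map <- rep("excluded", 12L)
  map[c(5, 6)] <- "breeding"
  map[c(12, 1, 2)] <- "winter"
  map[c(4, 9, 10, 11)] <- "migratory"
  names(map) <- as.character(1:12)
  map
}

#' Assign a season to each record from its month
#'
#' @param occ an [OccurrenceSet-class]; every record must have a month.
#' @param seasonMap month-to-season map, as from [defaultSeasonMap()]
#'   (overridable configuration).
#' @return the set with a `season` column filled in.
#' @export
assignSeason <- function(occ, seasonMap = defaultSeasonMap()) {
  rec <- occ@records
  if (any(!rec$month %in% 1:12)) stop("record month outside 1..12")
  rec$season <- unname(seasonMap[as.character(rec$month)])
  occurrenceSet(rec, provenance = occ@provenance)
}

#' Keep records spatially and seasonally unique
#'
#' At most one record per (grid cell, season); the earliest record in input
#' order is retained. Records outside the grid extent are dropped with a
#' warning, not silently.
#'
#' @param occ an [OccurrenceSet-class] with seasons assigned.
#' @param grid the [GridSpec-class] defining cells.
#' @return the deduplicated set (idempotent).
#' @export
dedupOccurrences <- function(occ, grid) {
  rec <- occ@records
  if (!"season" %in% names(rec)) stop("assign seasons before deduplicating")
  if (!nrow(rec)) return(occ)
  rc <- .cellFromXY(grid, rec$lon, rec$lat)
  outside <- is.na(rc[, "row"])
  if (any(outside)) {
    warning(sum(outside), " record(s) outside the raster extent dropped")
    rec <- rec[!outside, , drop = FALSE]
    rc <- rc[!outside, , drop = FALSE]
  }
  key <- paste(rc[, "row"], rc[, "col"], rec$season)
  dup <- duplicated(key)
  if (any(dup))
    message("dedupOccurrences: removed ", sum(dup), " duplicate record(s)")
  occurrenceSet(rec[!dup, , drop = FALSE], provenance = occ@provenance)
}

# Environment matrix for arbitrary (row, col) cells: one row per cell, one
# column per variable, values averaged over `months`. Rows with any nodata
# are dropped. Rownames are "row:col" cell keys.
.cellEnv <- function(stack, cells, months) {
  idx <- cbind(cells[, 1L], cells[, 2L])
  env <- sapply(.CLIMATE_VARIABLES, function(v) {
    acc <- 0
    for (m in months) acc <- acc + layerValues(stack, v, m)[idx]
    acc / length(months)
  })
  env <- matrix(env, ncol = length(.CLIMATE_VARIABLES),
                dimnames = list(paste(cells[, 1L], cells[, 2L], sep = ":"),
                                .CLIMATE_VARIABLES))
  env
}

#' Environment matrix of all (or selected) grid cells
#'
#' Per-variable values averaged over `months`, one row per non-nodata cell.
#' Used for backgrounds, modelling regions and niche-structure inputs.
#'
#' @param stack a [ClimateStack-class].
#' @param months months to average over (a season's months, or one month).
#' @param cells optional two-column (row, col) matrix restricting the cells.
#' @return numeric matrix, columns `tmax`, `tmin`, `prec`; rownames are
#'   `"row:col"` cell keys; rows with nodata removed.
#' @export
cellEnvMatrix <- function(stack, months, cells = NULL) {
  grid <- stack@grid
  if (is.null(cells))
    cells <- as.matrix(expand.grid(row = seq_len(grid@nRows), col = seq_len(grid@nCols)))
  env <- .cellEnv(stack, cells, months)
  keep <- stats::complete.cases(env)
  env[keep, , drop = FALSE]
}

#' Extract climate values at occurrence records
#'
#' Point-in-cell lookup (half-open cells, see [GridSpec-class]); for several
#' months the per-variable value is the mean over those months (season
#' composite). Records on nodata cells or outside the extent are dropped with
#' a logged count.
#'
#' @param stack a [ClimateStack-class].
#' @param occ an [OccurrenceSet-class].
#' @param months one month or a season's months.
#' @return numeric matrix (columns `tmax`, `tmin`, `prec`), rownames = record
#'   ids of the retained records.
#' @export
extractEnv <- function(stack, occ, months) {
  rec <- occ@records
  if (!all(months %in% stackMonths(stack)))
    stop("requested month(s) absent from stack: ",
         paste(setdiff(months, stackMonths(stack)), collapse = ", "))
  if (!nrow(rec)) stop("empty occurrence set")
  rc <- .cellFromXY(stack@grid, rec$lon, rec$lat)
  outside <- is.na(rc[, "row"])
  if (any(outside))
    warning(sum(outside), " record(s) outside the raster extent dropped")
  rc <- rc[!outside, , drop = FALSE]
  ids <- rec$id[!outside]
  if (!nrow(rc)) stop("no record falls inside the raster extent")
  env <- .cellEnv(stack, rc, months)
  rownames(env) <- ids
  onNodata <- !stats::complete.cases(env)
  if (any(onNodata))
    warning(sum(onNodata), " record(s) over nodata dropped")
  env <- env[!onNodata, , drop = FALSE]
  if (!nrow(env)) stop("no record left after nodata filtering")
  env
}
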