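# Niche breadth in a polar-coordinate climate space: project climate rows to
# 2-D by treating each variable as a force vector at a fixed angle, delimit
# the cloud with an alpha-hull, and measure area and directional overlap.
#
# The alpha-hull is computed from scratch: Bowyer-Watson Delaunay
# triangulation, then the alpha-shape keeps the triangles whose circumradius
# is at most alpha (alpha = Inf reproduces the convex hull).

#' Shared min-max scaling for polar projection
#'
#' Per-variable minima and maxima over the union of all stages being compared,
#' so every stage is projected into one polar space.
#'
#' @param envList list of environment matrices (same columns).
#' @return list with named `min` and `max` vectors.
#' @export
polarScaling <- function(envList) {
  all <- do.call(rbind, envList)
  list(min = apply(all, 2L, min), max = apply(all, 2L, max))
}

#' Project climate rows to polar coordinates
#'
#' Each variable is a force vector at a fixed angle; a row's point is the
#' equilibrium (vector sum): `X = sum_v x_v * cos(theta_v)`,
#' `Y = sum_v x_v * sin(theta_v)`. By default variables are min-max scaled to
#' `[0, 1]` (pass a shared [polarScaling()] when comparing stages, or
#' `scaling = NULL` for raw values) and angles are evenly spaced over
#' `[0, 2 * pi)` in column order.
#'
#' @param env environment matrix (>= 1 column).
#' @param angles named angles in radians, one per variable (default evenly
#'   spaced).
#' @param scaling list with `min`/`max` per variable, or `NULL` for raw
#'   values.
#' @return A [PolarCloud-class].
#' @export
polarCoordinates <- function(env, angles = NULL,
                             scaling = polarScaling(list(env))) {
  env <- as.matrix(env)
  if (ncol(env) < 1L) stop("need at least one variable")
  vars <- colnames(env)
  if (is.null(angles)) {
    angles <- 2 * pi * (seq_along(vars) - 1L) / length(vars)
    names(angles) <- vars
  }
  if (anyDuplicated(angles[vars])) stop("angles must be distinct per variable")
  if (!is.null(scaling)) {
    span <- scaling$max[vars] - scaling$min[vars]
    span[span == 0] <- 1  # constant variable: scaled value pinned below
    env <- sweep(sweep(env, 2L, scaling$min[vars]), 2L, span, "/")
  } else {
    scaling <- list(min = NULL, max = NULL)
  }
  pts <- cbind(
    X = as.vector(env %*% cos(angles[vars])),
    Y = as.vector(env %*% sin(angles[vars]))
  )
  new("PolarCloud", points = pts, angles = angles[vars], scaling = scaling)
}

# ---- Delaunay triangulation (Bowyer-Watson) --------------------------------

# circumcircle (cx, cy, r^2) of triangles given vertex coordinate matrices
.circum <- function(ax, ay, bx, by, cx, cy) {
  d <- 2 * (ax * (by - cy) + bx * (cy - ay) + cx * (ay - by))
  a2 <- ax^2 + ay^2; b2 <- bx^2 + by^2; c2 <- cx^2 + cy^2
  ux <- (a2 * (by - cy) + b2 * (cy - ay) + c2 * (ay - by)) / d
  uy <- (a2 * (cx - bx) + b2 * (ax - cx) + c2 * (bx - ax)) / d
  r2 <- (ux - ax)^2 + (uy - ay)^2
  r2[!is.finite(ux)] <- Inf  # degenerate (collinear) triangle: always "bad"
  cbind(ux, uy, r2)
}

# Delaunay triangle indices (m x 3) of a 2-D point set. A deterministic,
# index-based symbolic jitter breaks cocircular degeneracies (grid-derived
# clouds are full of them); triangle *membership* may depend on it but areas
# change by O(1e-8 * span) only.
.delaunay <- function(pts) {
  n <- nrow(pts)
  if (n < 3L) return(matrix(integer(), 0L, 3L))
  span <- max(diff(range(pts[, 1L])), diff(range(pts[, 2L])), 1e-12)
  i <- seq_len(n)
  P <- pts + cbind(((i * 2654435761) %% 65536) / 65536 - 0.5,
                   ((i * 1597334677) %% 65536) / 65536 - 0.5) * 1e-8 * span
  ctr <- c(mean(range(P[, 1L])), mean(range(P[, 2L])))
  # far enough out that no hull triangle's circumcircle reaches a super-vertex
  d <- span * 1e3
  V <- rbind(
    c(ctr[1] - 2 * d, ctr[2] - d),
    c(ctr[1] + 2 * d, ctr[2] - d),
    c(ctr[1], ctr[2] + 2 * d),
    P
  )
  cap <- 4L * n + 16L
  Tm <- matrix(NA_integer_, cap, 3L)
  CC <- matrix(NA_real_, cap, 3L)
  alive <- logical(cap)
  Tm[1L, ] <- 1:3
  CC[1L, ] <- .circum(V[1, 1], V[1, 2], V[2, 1], V[2, 2], V[3, 1], V[3, 2])
  alive[1L] <- TRUE
  nt <- 1L

  for (p in seq_len(n)) {
    vi <- p + 3L
    px <- V[vi, 1L]; py <- V[vi, 2L]
    act <- which(alive[seq_len(nt)])
    bad <- act[(CC[act, 1L] - px)^2 + (CC[act, 2L] - py)^2 < CC[act, 3L]]
    if (!length(bad)) next  # cannot happen for points inside the super-triangle
    e1 <- rbind(Tm[bad, c(1L, 2L), drop = FALSE],
                Tm[bad, c(2L, 3L), drop = FALSE],
                Tm[bad, c(3L, 1L), drop = FALSE])
    key <- paste(pmin(e1[, 1L], e1[, 2L]), pmax(e1[, 1L], e1[, 2L]))
    once <- !(key %in% key[duplicated(key)])
    alive[bad] <- FALSE
    hull <- e1[once, , drop = FALSE]
    nNew <- nrow(hull)
    if (nt + nNew > cap) {  # grow storage
      extra <- max(cap, nNew)
      Tm <- rbind(Tm, matrix(NA_integer_, extra, 3L))
      CC <- rbind(CC, matrix(NA_real_, extra, 3L))
      alive <- c(alive, logical(extra))
      cap <- cap + extra
    }
    idx <- nt + seq_len(nNew)
    Tm[idx, ] <- cbind(hull, vi)
    CC[idx, ] <- .circum(V[hull[, 1L], 1L], V[hull[, 1L], 2L],
                         V[hull[, 2L], 1L], V[hull[, 2L], 2L], px, py)
    alive[idx] <- TRUE
    nt <- nt + nNew
  }
  keep <- which(alive[seq_len(nt)])
  tri <- Tm[keep, , drop = FALSE]
  tri <- tri[rowSums(tri <= 3L) == 0L, , drop = FALSE]  # drop super-triangle
  tri - 3L
}

.triangleAreas <- function(pts, tri) {
  ax <- pts[tri[, 1L], 1L]; ay <- pts[tri[, 1L], 2L]
  bx <- pts[tri[, 2L], 1L]; by <- pts[tri[, 2L], 2L]
  cx <- pts[tri[, 3L], 1L]; cy <- pts[tri[, 3L], 2L]
  abs((bx - ax) * (cy - ay) - (cx - ax) * (by - ay)) / 2
}

.triangleCircumradii <- function(pts, tri) {
  a <- sqrt(rowSums((pts[tri[, 2L], , drop = FALSE] - pts[tri[, 3L], , drop = FALSE])^2))
  b <- sqrt(rowSums((pts[tri[, 1L], , drop = FALSE] - pts[tri[, 3L], , drop = FALSE])^2))
  cc <- sqrt(rowSums((pts[tri[, 1L], , drop = FALSE] - pts[tri[, 2L], , drop = FALSE])^2))
  area <- .triangleAreas(pts, tri)
  r <- a * b * cc / (4 * area)
  r[area == 0] <- Inf
  r
}

# Median nearest-neighbour distance. Near-coincident points (as produced by
# projecting neighbouring grid cells with almost identical climate) are
# collapsed first by snapping to 1/200 of the bounding-box diagonal --
# otherwise duplicate pairs drive the median to ~0 and the derived alpha
# filters away every triangle.
.medianNN <- function(pts, cap = 2000L) {
  diag <- sqrt(diff(range(pts[, 1L]))^2 + diff(range(pts[, 2L]))^2)
  if (diag == 0) return(0)
  snap <- diag / 200
  pts <- unique(round(pts / snap) * snap)
  n <- nrow(pts)
  if (n < 2L) return(snap)
  if (n > cap) pts <- pts[round(seq(1L, n, length.out = cap)), , drop = FALSE]
  D <- as.matrix(stats::dist(pts))
  diag(D) <- Inf
  stats::median(apply(D, 1L, min))
}

#' Alpha-hull of a polar cloud
#'
#' The alpha-shape of the points: the union of Delaunay triangles whose
#' circumradius is at most `alpha`. With `alpha = Inf` the shape is the convex
#' hull; small alpha follows concavities, avoiding overestimation of the
#' occupied climate area. Breadth is the shape's area.
#'
#' @param cloud a [PolarCloud-class] (>= 3 non-collinear points).
#' @param alpha positive radius; default 2x the median nearest-neighbour
#'   distance of the cloud (recorded in the result).
#' @return A [BreadthPolygon-class]. Degenerate (collinear) clouds give a
#'   zero-area result with a warning.
#' @export
alphaHull <- function(cloud, alpha = NULL) {
  pts <- cloud@points
  if (is.null(alpha)) alpha <- 2 * .medianNN(pts)
  if (nrow(pts) < 3L) {
    warning("fewer than 3 points: zero-area hull")
    return(new("BreadthPolygon", triangles = matrix(integer(), 0L, 3L),
               points = pts, alpha = alpha, area = 0))
  }
  tri <- .delaunay(pts)
  if (nrow(tri)) {
    r <- .triangleCircumradii(pts, tri)
    tri <- tri[r <= alpha, , drop = FALSE]
  }
  area <- if (nrow(tri)) sum(.triangleAreas(pts, tri)) else 0
  if (area == 0)
    warning("degenerate (collinear or over-tight alpha) cloud: zero-area hull")
  new("BreadthPolygon", triangles = tri, points = pts,
      alpha = alpha, area = area)
}

# TRUE for query points inside any kept triangle (barycentric sign test,
# per-triangle restricted to its bounding box)
.inAlphaShape <- function(poly, qx, qy) {
  inside <- rep(FALSE, length(qx))
  pts <- poly@points
  tri <- poly@triangles
  eps <- 1e-12
  for (t in seq_len(nrow(tri))) {
    a <- pts[tri[t, 1L], ]; b <- pts[tri[t, 2L], ]; cc <- pts[tri[t, 3L], ]
    cand <- which(!inside &
                  qx >= min(a[1], b[1], cc[1]) - eps & qx <= max(a[1], b[1], cc[1]) + eps &
                  qy >= min(a[2], b[2], cc[2]) - eps & qy <= max(a[2], b[2], cc[2]) + eps)
    if (!length(cand)) next
    d1 <- (qx[cand] - b[1]) * (a[2] - b[2]) - (a[1] - b[1]) * (qy[cand] - b[2])
    d2 <- (qx[cand] - cc[1]) * (b[2] - cc[2]) - (b[1] - cc[1]) * (qy[cand] - cc[2])
    d3 <- (qx[cand] - a[1]) * (cc[2] - a[2]) - (cc[1] - a[1]) * (qy[cand] - a[2])
    neg <- (d1 < -eps) | (d2 < -eps) | (d3 < -eps)
    pos <- (d1 > eps) | (d2 > eps) | (d3 > eps)
    inside[cand[!(neg & pos)]] <- TRUE
  }
  inside
}

#' Directional breadth overlap on a shared lattice
#'
#' Rasterizes both polygons onto one evaluation lattice spanning their joint
#' bounding box (a cell counts if its centre lies inside);
#' `overlap(a -> b) = 100 * |cells(a) intersect cells(b)| / |cells(a)|`.
#' Occupied-cell counts are the "pixel" breadths.
#'
#' @param a,b [BreadthPolygon-class] objects in the same polar space.
#' @param n lattice resolution (n x n, default 100).
#' @return list: `a_to_b`, `b_to_a` (percentages, `NA` if a polygon
#'   rasterizes to nothing), `pixelsA`, `pixelsB`, `intersection`.
#' @export
breadthOverlap <- function(a, b, n = 100L) {
  allPts <- rbind(a@points, b@points)
  xr <- range(allPts[, 1L]); yr <- range(allPts[, 2L])
  dx <- diff(xr) / n; dy <- diff(yr) / n
  cx <- xr[1L] + (seq_len(n) - 0.5) * dx
  cy <- yr[1L] + (seq_len(n) - 0.5) * dy
  g <- expand.grid(x = cx, y = cy)
  inA <- .inAlphaShape(a, g$x, g$y)
  inB <- .inAlphaShape(b, g$x, g$y)
  nA <- sum(inA); nB <- sum(inB); nAB <- sum(inA & inB)
  if (nA == 0L || nB == 0L)
    warning("a polygon rasterized to zero cells on the evaluation lattice")
  list(
    a_to_b = if (nA == 0L) NA_real_ else 100 * nAB / nA,
    b_to_a = if (nB == 0L) NA_real_ else 100 * nAB / nB,
    pixelsA = nA, pixelsB = nB, intersection = nAB
  )
}
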