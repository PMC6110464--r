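test_that("polar projection is the vector sum of variable force vectors", {
  # one variable at angle 0: the raw value itself
  p1 <- polarCoordinates(matrix(2.5, 1, 1, dimnames = list(NULL, "v")),
                         angles = c(v = 0), scaling = NULL)
  expect_equal(unname(p1@points[1, ]), c(2.5, 0))
  # two equal opposing vectors cancel
  p2 <- polarCoordinates(matrix(c(3, 3), 1, 2, dimnames = list(NULL, c("a", "b"))),
                         angles = c(a = 0, b = pi), scaling = NULL)
  expect_equal(unname(p2@points[1, ]), c(0, 0), tolerance = 1e-12)
  # three variables against a hand-computed trigonometric sum
  set.seed(3)
  env <- matrix(runif(30), 10, 3, dimnames = list(NULL, c("tmax", "tmin", "prec")))
  ang <- c(tmax = 0, tmin = 2 * pi / 3, prec = 4 * pi / 3)
  pc <- polarCoordinates(env, angles = ang, scaling = NULL)
  byHand <- t(apply(env, 1, function(r)
    c(sum(r * cos(ang)), sum(r * sin(ang)))))
  expect_equal(unname(pc@points), unname(byHand), tolerance = 1e-12)
  # default min-max scaling maps each variable onto [0, 1]
  sc <- polarCoordinates(env)
  expect_equal(unname(sc@scaling$min), apply(env, 2, min), ignore_attr = TRUE)
})

test_that("large-alpha hulls equal the convex hull", {
  sq <- matrix(c(0, 0, 1, 0, 1, 1, 0, 1), 4, 2, byrow = TRUE)
  cloud <- new("PolarCloud", points = sq, angles = c(a = 0), scaling = list())
  h <- alphaHull(cloud, alpha = Inf)
  expect_equal(breadthArea(h), 1, tolerance = 1e-6)
  # random cloud: area equals an independent convex-hull oracle
  set.seed(4)
  pts <- cbind(rnorm(120), rnorm(120))
  cl <- new("PolarCloud", points = pts, angles = c(a = 0), scaling = list())
  expect_equal(breadthArea(alphaHull(cl, alpha = Inf)), chullArea(pts),
               tolerance = 1e-6)
})

test_that("small alpha captures concavities the convex hull overestimates", {
  # C-shaped cloud
  set.seed(5)
  t <- runif(400, 0.6 * pi, 2.8 * pi / 1.4)
  r <- runif(400, 0.7, 1)
  pts <- cbind(r * cos(t), r * sin(t))
  cl <- new("PolarCloud", points = pts, angles = c(a = 0), scaling = list())
  tight <- alphaHull(cl, alpha = 0.3)
  expect_lt(breadthArea(tight), chullArea(pts))
  expect_gt(breadthArea(tight), 0)
  # alpha-hull area never exceeds the convex hull area
  for (s in 1:5) {
    set.seed(s)
    p <- cbind(runif(80), runif(80))
    c2 <- new("PolarCloud", points = p, angles = c(a = 0), scaling = list())
    expect_lte(breadthArea(alphaHull(c2)), chullArea(p) + 1e-9)
  }
})

test_that("degenerate clouds give a zero-area hull with a warning", {
  line <- cbind(1:5, 2 * (1:5))
  cl <- new("PolarCloud", points = line, angles = c(a = 0), scaling = list())
  expect_warning(h <- alphaHull(cl, alpha = Inf), "degenerate|fewer")
  expect_equal(breadthArea(h), 0)
})

test_that("breadth is invariant under a global rotation of the angle map", {
  set.seed(6)
  env <- matrix(runif(600, 0, 10), 200, 3,
                dimnames = list(NULL, c("tmax", "tmin", "prec")))
  base <- c(tmax = 0, tmin = 2 * pi / 3, prec = 4 * pi / 3)
  a1 <- alphaHull(polarCoordinates(env, angles = base), alpha = Inf)
  a2 <- alphaHull(polarCoordinates(env, angles = base + 0.7), alpha = Inf)
  expect_equal(breadthArea(a1), breadthArea(a2), tolerance = 1e-6)
})

test_that("directional overlap follows containment arithmetic", {
  fine <- as.matrix(expand.grid(x = seq(0, 1, by = 0.02),
                                y = seq(0, 1, by = 0.02)))
  quarter <- fine[fine[, 1] <= 0.5 & fine[, 2] <= 0.5, ]
  a <- alphaHull(new("PolarCloud", points = fine, angles = c(a = 0),
                     scaling = list()), alpha = Inf)
  b <- alphaHull(new("PolarCloud", points = quarter, angles = c(a = 0),
                     scaling = list()), alpha = Inf)
  ov <- breadthOverlap(a, b, n = 100)
  expect_equal(ov$b_to_a, 100)
  expect_equal(ov$a_to_b, 25)
  # identical polygons overlap fully both ways
  self <- breadthOverlap(a, a, n = 50)
  expect_equal(c(self$a_to_b, self$b_to_a), c(100, 100))
  # directionality identity: both directions recover the intersection count
  expect_equal(ov$a_to_b * ov$pixelsA, ov$b_to_a * ov$pixelsB)
})

test_that("rasterized overlap matches an exhaustive point-in-polygon scan", {
  set.seed(7)
  pa <- cbind(runif(60, 0, 1), runif(60, 0, 1))
  pb <- cbind(runif(60, 0.4, 1.4), runif(60, 0.3, 1.3))
  a <- alphaHull(new("PolarCloud", points = pa, angles = c(a = 0),
                     scaling = list()), alpha = Inf)
  b <- alphaHull(new("PolarCloud", points = pb, angles = c(a = 0),
                     scaling = list()), alpha = Inf)
  n <- 60
  ov <- breadthOverlap(a, b, n = n)
  # oracle: test every lattice-cell centre against both convex hulls with a
  # sign test on the clockwise-ordered hull edges
  allp <- rbind(pa, pb)
  xr <- range(allp[, 1]); yr <- range(allp[, 2])
  cx <- xr[1] + (seq_len(n) - 0.5) * diff(xr) / n
  cy <- yr[1] + (seq_len(n) - 0.5) * diff(yr) / n
  g <- expand.grid(x = cx, y = cy)
  crossSign <- function(pts) {
    h <- grDevices::chull(pts)
    x <- pts[h, 1]; y <- pts[h, 2]
    sum((x[c(2:length(x), 1)] - x) * (y[c(2:length(y), 1)] + y))
  }
  inHullCW <- function(pts, qx, qy) {
    h <- grDevices::chull(pts)
    poly <- pts[h, , drop = FALSE]
    if (crossSign(pts) < 0) poly <- poly[rev(seq_len(nrow(poly))), ]
    m <- nrow(poly)
    ins <- rep(TRUE, length(qx))
    for (i in seq_len(m)) {
      j <- if (i == m) 1L else i + 1L
      cr <- (poly[j, 1] - poly[i, 1]) * (qy - poly[i, 2]) -
            (poly[j, 2] - poly[i, 2]) * (qx - poly[i, 1])
      ins <- ins & (cr <= 1e-12)
    }
    ins
  }
  inA <- inHullCW(pa, g$x, g$y)
  inB <- inHullCW(pb, g$x, g$y)
  expect_equal(ov$pixelsA, sum(inA))
  expect_equal(ov$pixelsB, sum(inB))
  expect_equal(ov$a_to_b, 100 * sum(inA & inB) / sum(inA))
})
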