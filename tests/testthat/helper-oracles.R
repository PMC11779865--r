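# Independent oracles used across the suite. These deliberately use
# plain loops and direct enumeration, not the package's code paths.

# O(n^2) nearest-neighbour distances by explicit double loop.
bruteNN <- function(from, to, excludeIdx = FALSE) {
  out <- numeric(nrow(from))
  for (i in seq_len(nrow(from))) {
    best <- Inf
    for (j in seq_len(nrow(to))) {
      if (excludeIdx && i == j) next
      d <- sqrt((from[i, 1] - to[j, 1])^2 + (from[i, 2] - to[j, 2])^2)
      if (d < best) best <- d
    }
    out[i] <- best
  }
  out
}

# Mean NN statistic for a labelling, by brute force.
bruteNNStat <- function(xy, lab, fromType, toType) {
  fr <- xy[lab == fromType, , drop = FALSE]
  to <- xy[lab == toType, , drop = FALSE]
  if (fromType == toType) {
    mean(bruteNN(fr, to, excludeIdx = TRUE))
  } else {
    mean(bruteNN(fr, to))
  }
}

# All distinct permutations of a label multiset (recursive construction).
multisetPermutations <- function(labels) {
  counts <- table(labels)
  lev <- names(counts)
  res <- list()
  build <- function(prefix, remaining) {
    if (sum(remaining) == 0L) {
      res[[length(res) + 1L]] <<- prefix
      return(invisible())
    }
    for (k in seq_along(lev)) {
      if (remaining[k] > 0L) {
        r2 <- remaining
        r2[k] <- r2[k] - 1L
        build(c(prefix, lev[k]), r2)
      }
    }
  }
  build(character(0), as.integer(counts))
  res
}

# Exhaustive permutation-null mean and population SD by enumerating every
# distinct assignment of the full label multiset.
bruteExhaustiveNull <- function(xy, lab, fromType, toType) {
  perms <- multisetPermutations(lab)
  stats <- vapply(perms, function(p) bruteNNStat(xy, p, fromType, toType),
                  numeric(1))
  list(mean = mean(stats), sd = sqrt(mean((stats - mean(stats))^2)),
       n = length(stats))
}

# Raster point-in-polygon oracle: classify each point by the pixel mask
# of the hulls at the given resolution (even-odd fill, computed with
# polygon-free arithmetic per pixel centre).
rasterAssignOracle <- function(pts, hulls, res = 0.5) {
  insideRing <- function(px, py, ring) {
    n <- nrow(ring)
    inside <- FALSE
    j <- n
    for (i in seq_len(n)) {
      if ((ring[i, 2] > py) != (ring[j, 2] > py)) {
        xint <- (ring[j, 1] - ring[i, 1]) * (py - ring[i, 2]) /
          (ring[j, 2] - ring[i, 2]) + ring[i, 1]
        if (px < xint) inside <- !inside
      }
      j <- i
    }
    inside
  }
  areas <- vapply(hulls, hullArea, numeric(1))
  out <- rep(NA_integer_, nrow(pts))
  for (k in seq_len(nrow(pts))) {
    # snap to the centre of the containing pixel
    px <- (floor(pts[k, 1] / res) + 0.5) * res
    py <- (floor(pts[k, 2] / res) + 0.5) * res
    best <- NA_integer_; bestArea <- Inf
    for (i in seq_along(hulls)) {
      h <- hulls[[i]]
      parity <- insideRing(px, py, h@exterior)
      for (hole in h@holes) parity <- xor(parity, insideRing(px, py, hole))
      if (parity && areas[i] < bestArea) {
        best <- i; bestArea <- areas[i]
      }
    }
    out[k] <- best
  }
  out
}

# Matern II hard-core process: CSR proposals with random marks, keep a
# point when no earlier-marked point lies within r.
rMaternII <- function(intensityPerMm2, r, w, h) {
  n <- rpois(1L, intensityPerMm2 * 1e-6 * w * h)
  if (n == 0L) return(cbind(numeric(0), numeric(0)))
  x <- runif(n, 0, w); y <- runif(n, 0, h); mark <- runif(n)
  keep <- rep(TRUE, n)
  for (i in seq_len(n)) {
    for (j in seq_len(n)) {
      if (i != j && mark[j] < mark[i] &&
          (x[i] - x[j])^2 + (y[i] - y[j])^2 < r^2) {
        keep[i] <- FALSE
        break
      }
    }
  }
  cbind(x[keep], y[keep])
}

# Small Thomas-process T cell layer plus CSR background, for sign checks.
clusteredScene <- function(nParents = 8, offspring = 8, sigma = 20,
                           nBackground = 240, w = 1000, h = 1000) {
  px <- runif(nParents, 0, w); py <- runif(nParents, 0, h)
  tx <- rep(px, each = offspring) + rnorm(nParents * offspring, 0, sigma)
  ty <- rep(py, each = offspring) + rnorm(nParents * offspring, 0, sigma)
  ok <- tx >= 0 & tx <= w & ty >= 0 & ty <= h
  bg <- cbind(runif(nBackground, 0, w), runif(nBackground, 0, h))
  CellMap(data.frame(
    x = c(tx[ok], bg[, 1]), y = c(ty[ok], bg[, 2]),
    phenotype = c(rep("CD8T", sum(ok)), rep("Other", nBackground))))
}

# Square hull helper.
squareHull <- function(x0, y0, side, marker = "LAMA2") {
  MembraneHull(cbind(c(x0, x0 + side, x0 + side, x0),
                     c(y0, y0, y0 + side, y0 + side)), marker = marker)
}

# Annulus (outer circle with concentric hole).
annulusHull <- function(cx, cy, rIn, rOut, marker = "LAMA2") {
  MembraneHull(circleRingT(cx, cy, rOut),
               holes = list(circleRingT(cx, cy, rIn)), marker = marker)
}

circleRingT <- function(cx, cy, r, n = 72) {
  th <- seq(0, 2 * pi, length.out = n + 1)[-(n + 1)]
  cbind(cx + r * cos(th), cy + r * sin(th))
}

# Rotate a ring about its vertex centroid (test-side copy).
rotateRingT <- function(ring, deg) {
  th <- deg * pi / 180
  c0 <- colMeans(ring)
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sweep(ring, 2, c0) %*% t(R), 2, c0, "+")
}

# Distance from one point to a segment (test-side copy).
segDistT <- function(p, a, b) {
  v <- b - a; w <- p - a
  len2 <- sum(v * v)
  t <- if (len2 > 0) min(1, max(0, sum(w * v) / len2)) else 0
  sqrt(sum((w - t * v)^2))
}

# Minimum distance from points to any ring edge of a hull list.
minEdgeDistT <- function(pts, hulls) {
  vapply(seq_len(nrow(pts)), function(i) {
    min(vapply(hulls, function(h) {
      rings <- c(list(h@exterior), h@holes)
      min(vapply(rings, function(r) {
        n <- nrow(r); dmin <- Inf; j <- n
        for (ii in seq_len(n)) {
          dmin <- min(dmin, segDistT(pts[i, ], r[j, ], r[ii, ]))
          j <- ii
        }
        dmin
      }, numeric(1)))
    }, numeric(1)))
  }, numeric(1))
}
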