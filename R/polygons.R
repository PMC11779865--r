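# Planar polygon primitives. Rings are open n x 2 matrices (closing edge
# implicit); containment is even-odd with boundary points inclusive.

# Signed shoelace area of one ring.
ringArea <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  sum(x * yn - xn * y) / 2
}

ringCentroid <- function(ring) {
  x <- ring[, 1]; y <- ring[, 2]
  xn <- c(x[-1], x[1]); yn <- c(y[-1], y[1])
  cr <- x * yn - xn * y
  a <- sum(cr) / 2
  if (abs(a) < 1e-12) return(colMeans(ring))
  c(sum((x + xn) * cr), sum((y + yn) * cr)) / (6 * a)
}

# Crossing-number parity of points against one ring (vectorised over
# points). Boundary handling is delegated to onRingBoundary.
ringCrossings <- function(pts, ring) {
  n <- nrow(ring)
  px <- pts[, 1]; py <- pts[, 2]
  inside <- integer(length(px))
  j <- n
  for (i in seq_len(n)) {
    xi <- ring[i, 1]; yi <- ring[i, 2]
    xj <- ring[j, 1]; yj <- ring[j, 2]
    crosses <- ((yi > py) != (yj > py)) &
      (px < (xj - xi) * (py - yi) / (yj - yi) + xi)
    inside <- inside + as.integer(crosses)
    j <- i
  }
  inside
}

# TRUE where a point lies on a ring edge, within tol.
onRingBoundary <- function(pts, ring, tol = 1e-9) {
  n <- nrow(ring)
  on <- rep(FALSE, nrow(pts))
  j <- n
  for (i in seq_len(n)) {
    d <- pointSegmentDistance(pts, ring[j, ], ring[i, ])
    on <- on | (d <= tol)
    j <- i
  }
  on
}

# Distance from each point to segment a-b.
pointSegmentDistance <- function(pts, a, b) {
  vx <- b[1] - a[1]; vy <- b[2] - a[2]
  wx <- pts[, 1] - a[1]; wy <- pts[, 2] - a[2]
  len2 <- vx * vx + vy * vy
  t <- if (len2 > 0) pmin(1, pmax(0, (wx * vx + wy * vy) / len2)) else 0
  dx <- wx - t * vx; dy <- wy - t * vy
  sqrt(dx * dx + dy * dy)
}

#' Even-odd containment test against a hull
#'
#' Tests each point against the hull's exterior ring and holes using the
#' even-odd rule; points on any ring boundary count as contained unless
#' they fall on a hole's boundary from inside the hole, in which case the
#' inclusive convention still reports contained.
#'
#' @param hull a \code{MembraneHull}.
#' @param pts n x 2 matrix of points (micrometres).
#' @return logical vector.
#' @export
hullContains <- function(hull, pts) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  cross <- ringCrossings(pts, hull@exterior)
  for (h in hull@holes) cross <- cross + ringCrossings(pts, h)
  inside <- (cross %% 2L) == 1L
  bnd <- onRingBoundary(pts, hull@exterior)
  for (h in hull@holes) bnd <- bnd | onRingBoundary(pts, h)
  inside | bnd
}

#' Distance from points to the nearest hull of a list
#'
#' Euclidean distance from each point to the nearest point of any hull;
#' zero for points contained in a hull.
#'
#' @param pts n x 2 matrix (micrometres).
#' @param hulls list of \code{MembraneHull}.
#' @return numeric vector of distances (micrometres).
#' @export
distanceToHulls <- function(pts, hulls) {
  pts <- matrix(as.numeric(pts), ncol = 2)
  if (length(hulls) == 0L) stop("no hulls supplied")
  d <- rep(Inf, nrow(pts))
  for (hull in hulls) {
    rings <- c(list(hull@exterior), hull@holes)
    dh <- rep(Inf, nrow(pts))
    for (ring in rings) {
      n <- nrow(ring)
      j <- n
      for (i in seq_len(n)) {
        dh <- pmin(dh, pointSegmentDistance(pts, ring[j, ], ring[i, ]))
        j <- i
      }
    }
    dh[hullContains(hull, pts)] <- 0
    d <- pmin(d, dh)
  }
  d
}

# Regular polygon approximating a circle, used for simulated vessels.
circleRing <- function(center, radius, n = 64L) {
  th <- seq(0, 2 * pi, length.out = n + 1L)[-(n + 1L)]
  cbind(center[1] + radius * cos(th), center[2] + radius * sin(th))
}

#' Read a GeoJSON FeatureCollection of membrane/vessel polygons
#'
#' Ingests QuPath-style GeoJSON exports. Polygon features become one
#' \code{MembraneHull} each (holes preserved); MultiPolygon features are
#' split into one hull per part. Features with other geometry types are
#' skipped with a single counted warning.
#'
#' @param path GeoJSON file.
#' @param marker marker label to assign; when \code{NULL} it is read per
#'   feature from \code{propertyKey} (QuPath's nested
#'   \code{classification$name} is understood).
#' @param propertyKey property holding the marker label.
#' @return list of \code{MembraneHull}; attribute \code{"n_skipped"}
#'   counts skipped non-polygon features.
#' @export
readPolygonCollection <- function(path, marker = NULL,
                                  propertyKey = "classification") {
  if (!file.exists(path)) stop("file not found: ", path)
  gj <- jsonlite::read_json(path, simplifyVector = FALSE)
  feats <- if (identical(gj$type, "FeatureCollection")) gj$features
           else list(gj)
  hulls <- list()
  skipped <- 0L
  for (f in feats) {
    geom <- if (identical(f$type, "Feature")) f$geometry else f
    mk <- marker
    if (is.null(mk)) {
      p <- f$properties[[propertyKey]]
      mk <- if (is.list(p)) p$name else p
      if (is.null(mk)) mk <- "unknown"
    }
    if (identical(geom$type, "Polygon")) {
      hulls <- c(hulls, list(geojsonRingsToHull(geom$coordinates, mk)))
    } else if (identical(geom$type, "MultiPolygon")) {
      for (part in geom$coordinates)
        hulls <- c(hulls, list(geojsonRingsToHull(part, mk)))
    } else {
      skipped <- skipped + 1L
    }
  }
  if (skipped > 0L)
    warning(sprintf("skipped %d non-polygon feature(s)", skipped))
  attr(hulls, "n_skipped") <- skipped
  hulls
}

geojsonRingsToHull <- function(rings, marker) {
  mats <- lapply(rings, function(r) {
    m <- do.call(rbind, lapply(r, function(xy) as.numeric(xy[1:2])))
    if (nrow(m) < 4L)
      stop("invalid ring: fewer than 3 distinct vertices")
    m
  })
  MembraneHull(mats[[1]], holes = mats[-1], marker = marker)
}

#' Write hulls as a GeoJSON FeatureCollection
#'
#' Inverse of \code{\link{readPolygonCollection}}; rings are closed on
#' output, markers stored under \code{classification$name}.
#'
#' @param hulls list of \code{MembraneHull}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writePolygonCollection <- function(hulls, path) {
  closeRing <- function(m) {
    m <- rbind(m, m[1, ])
    lapply(seq_len(nrow(m)), function(i) c(m[i, 1], m[i, 2]))
  }
  feats <- lapply(hulls, function(h) {
    list(type = "Feature",
         properties = list(classification = list(name = h@marker)),
         geometry = list(
           type = "Polygon",
           coordinates = c(list(closeRing(h@exterior)),
                           lapply(h@holes, closeRing))))
  })
  jsonlite::write_json(list(type = "FeatureCollection", features = feats),
                       path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
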