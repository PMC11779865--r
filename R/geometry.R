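#' @importFrom EBImage dilate erode makeBrush bwlabel ocontour
NULL

# Rasterize hulls (even-odd, holes respected) on a regular grid of pixel
# centres. Returns list(mask, origin, res); mask[ix, iy] with centre at
# origin + (c(ix, iy) - 0.5) * res.
rasterizeHulls <- function(hulls, res, bbox) {
  nx <- max(1L, ceiling((bbox[2] - bbox[1]) / res))
  ny <- max(1L, ceiling((bbox[4] - bbox[3]) / res))
  cx <- bbox[1] + (seq_len(nx) - 0.5) * res
  cy <- bbox[3] + (seq_len(ny) - 0.5) * res
  pts <- cbind(rep(cx, times = ny), rep(cy, each = nx))
  mask <- rep(FALSE, nx * ny)
  for (h in hulls) {
    cross <- ringCrossings(pts, h@exterior)
    for (hole in h@holes) cross <- cross + ringCrossings(pts, hole)
    mask <- mask | ((cross %% 2L) == 1L)
  }
  list(mask = matrix(mask, nrow = nx, ncol = ny),
       origin = c(bbox[1], bbox[3]), res = res)
}

# Douglas-Peucker simplification of an open chain.
dpChain <- function(pts, tol) {
  n <- nrow(pts)
  if (n <= 2L) return(pts)
  d <- pointSegmentDistance(pts[2:(n - 1), , drop = FALSE],
                            pts[1, ], pts[n, ])
  i <- which.max(d)
  if (d[i] <= tol) return(pts[c(1L, n), , drop = FALSE])
  k <- i + 1L
  left <- dpChain(pts[1:k, , drop = FALSE], tol)
  right <- dpChain(pts[k:n, , drop = FALSE], tol)
  rbind(left[-nrow(left), , drop = FALSE], right)
}

# Simplify a closed ring: split at the two mutually farthest-ish anchor
# vertices and simplify each half.
simplifyRing <- function(ring, tol) {
  n <- nrow(ring)
  if (n <= 4L || tol <= 0) return(ring)
  d1 <- (ring[, 1] - ring[1, 1])^2 + (ring[, 2] - ring[1, 2])^2
  j <- which.max(d1)
  if (j <= 2L || j >= n) return(ring)
  a <- dpChain(ring[1:j, , drop = FALSE], tol)
  b <- dpChain(ring[j:n, , drop = FALSE], tol)
  out <- rbind(a[-nrow(a), , drop = FALSE], b[-nrow(b), , drop = FALSE])
  if (nrow(out) < 3L) ring else out
}

#' Build smoothed membrane hulls by morphological closing
#'
#' Converts raw membrane polygons into closed hulls: nearby fragments
#' separated by less than the smoothing radius merge into one hull, while
#' far-apart objects stay separate. The closing is computed on a raster
#' (dilation followed by a one-pixel-smaller erosion, so the input is
#' always contained in the output), connected components are labelled,
#' and each component's outer contour is traced and simplified.
#'
#' @param polygons list of \code{MembraneHull} (holes are honoured during
#'   rasterisation; outputs are single rings) or raw n x 2 vertex
#'   matrices; zero-area inputs are skipped with a warning.
#' @param smoothing closing radius (micrometres).
#' @param resolution raster resolution (micrometres); default
#'   \code{smoothing / 5}.
#' @return list of \code{MembraneHull}, one per connected component,
#'   carrying the marker of the first input.
#' @export
buildHulls <- function(polygons, smoothing, resolution = NULL) {
  if (smoothing <= 0) stop("smoothing must be positive")
  keep <- vapply(polygons, function(p) {
    if (is(p, "MembraneHull")) hullArea(p) > 0
    else nrow(p) >= 3L && abs(ringArea(as.matrix(p))) > 0
  }, logical(1))
  if (any(!keep))
    warning(sprintf("skipped %d degenerate zero-area polygon(s)",
                    sum(!keep)))
  polygons <- lapply(polygons[keep], function(p)
    if (is(p, "MembraneHull")) p else MembraneHull(as.matrix(p)))
  if (length(polygons) == 0L) return(list())
  res <- if (is.null(resolution)) smoothing / 5 else resolution
  allv <- do.call(rbind, lapply(polygons, function(p) p@exterior))
  pad <- smoothing + 2 * res
  bbox <- c(min(allv[, 1]) - pad, max(allv[, 1]) + pad,
            min(allv[, 2]) - pad, max(allv[, 2]) + pad)
  ras <- rasterizeHulls(polygons, res, bbox)
  k <- max(1L, round(smoothing / res))
  m <- matrix(as.numeric(ras$mask), nrow = nrow(ras$mask))
  m <- dilate(m, makeBrush(2L * k + 1L, "disc"))
  ke <- max(k - 1L, 0L)
  if (ke > 0L) m <- erode(m, makeBrush(2L * ke + 1L, "disc"))
  lab <- bwlabel(m)
  contours <- ocontour(lab)
  mk <- polygons[[1]]@marker
  out <- lapply(contours, function(cc) {
    ring <- cbind(ras$origin[1] + (cc[, 1] + 0.5) * res,
                  ras$origin[2] + (cc[, 2] + 0.5) * res)
    ring <- simplifyRing(ring, res / 2)
    if (nrow(ring) < 3L || abs(ringArea(ring)) <= 0) return(NULL)
    MembraneHull(ring, marker = mk)
  })
  out[!vapply(out, is.null, logical(1))]
}

#' Assign cells to hulls by centroid containment
#'
#' Even-odd containment of each cell centroid, boundary inclusive; a cell
#' inside the hole of an annulus is not assigned. Cells contained in
#' several (nested) hulls are assigned to the smallest-area one.
#'
#' @param cells a \code{CellMap} or n x 2 coordinate matrix.
#' @param hulls list of \code{MembraneHull}.
#' @return integer vector of hull indices (NA for unassigned), named by
#'   cell id when available.
#' @export
assignCellsToHulls <- function(cells, hulls) {
  xy <- if (is(cells, "CellMap")) coords(cells) else
    matrix(as.numeric(cells), ncol = 2)
  ids <- if (is(cells, "CellMap")) cellData(cells)$cell_id else NULL
  n <- nrow(xy)
  assign <- rep(NA_integer_, n)
  if (length(hulls)) {
    areas <- vapply(hulls, hullArea, numeric(1))
    bestArea <- rep(Inf, n)
    for (i in seq_along(hulls)) {
      inside <- hullContains(hulls[[i]], xy)
      upd <- inside & (areas[i] < bestArea)
      assign[upd] <- i
      bestArea[upd] <- areas[i]
    }
  }
  if (!is.null(ids)) names(assign) <- ids
  assign
}

#' Detect perivascular T cell cuffs
#'
#' A cuff is a membrane hull containing more than two T cells (i.e. at
#' least three), counting centroids of cells whose phenotype is in
#' \code{tLabels}. The cuff's equivalent radius is
#' \code{sqrt(area / pi)}; a size class is assigned from configurable
#' radius cutoffs.
#'
#' @param cells a \code{CellMap}.
#' @param hulls list of membrane \code{MembraneHull}s.
#' @param tLabels phenotype labels counted as T cells.
#' @param radiusCutoffs increasing equivalent-radius cutoffs (micrometres)
#'   separating size classes small / medium / large.
#' @return data.frame with one row per cuff: \code{hull_id} (index into
#'   \code{hulls}), \code{t_cell_count}, \code{area} (um^2),
#'   \code{equivalent_radius} (um), \code{size_class}, and a list column
#'   \code{members} of member cell ids.
#' @export
detectCuffs <- function(cells, hulls, tLabels = tCellLabels(),
                        radiusCutoffs = c(50, 100)) {
  if (length(tLabels) == 0L) stop("tLabels must be non-empty")
  empty <- data.frame(hull_id = integer(0), t_cell_count = integer(0),
                      area = numeric(0), equivalent_radius = numeric(0),
                      size_class = character(0))
  empty$members <- list()
  if (length(hulls) == 0L || nCells(cells) == 0L) return(empty)
  tc <- cells[phenotypes(cells) %in% tLabels]
  if (nCells(tc) == 0L) return(empty)
  assign <- assignCellsToHulls(tc, hulls)
  counts <- table(assign)
  cuffIds <- as.integer(names(counts)[counts >= 3L])
  if (length(cuffIds) == 0L) return(empty)
  ids <- cellData(tc)$cell_id
  out <- data.frame(
    hull_id = cuffIds,
    t_cell_count = as.integer(counts[as.character(cuffIds)]),
    area = vapply(hulls[cuffIds], hullArea, numeric(1)))
  out$equivalent_radius <- sqrt(out$area / pi)
  classes <- c("small", "medium", "large")[
    findInterval(out$equivalent_radius, radiusCutoffs) + 1L]
  out$size_class <- classes
  out$members <- lapply(cuffIds, function(i)
    ids[!is.na(assign) & assign == i])
  rownames(out) <- NULL
  out
}

#' Area-adjusted cell count in a region
#'
#' Count of cells of the given label(s) whose centroid lies in the
#' region, divided by the region area in mm^2.
#'
#' @param cells a \code{CellMap}.
#' @param region a \code{MembraneHull}.
#' @param label phenotype label(s) to count; NULL counts all cells.
#' @return cells per mm^2.
#' @export
areaAdjustedCount <- function(cells, region, label = NULL) {
  a <- hullArea(region)
  if (!is.finite(a) || a <= 0) stop("region area must be positive")
  sel <- if (is.null(label)) rep(TRUE, nCells(cells)) else
    phenotypes(cells) %in% label
  if (!any(sel)) return(0)
  n <- sum(hullContains(region, coords(cells)[sel, , drop = FALSE]))
  n / (a * 1e-6)
}

#' Classify the tissue phenotype of an ROI
#'
#' \code{"cuff"} when at least one detected cuff is present,
#' \code{"stromal_T"} when T cells are present without a cuff, and
#' \code{"absent"} when the ROI has no T cells.
#'
#' @param roiCells \code{CellMap} of the ROI.
#' @param cuffs cuff table from \code{\link{detectCuffs}} run on the ROI.
#' @param tLabels phenotype labels counted as T cells.
#' @return one of "cuff", "stromal_T", "absent".
#' @export
classifyROIPhenotype <- function(roiCells, cuffs,
                                 tLabels = tCellLabels()) {
  if (!is.null(cuffs) && nrow(cuffs) >= 1L) return("cuff")
  if (any(phenotypes(roiCells) %in% tLabels)) return("stromal_T")
  "absent"
}

rotateRing <- function(ring, angleDeg, center) {
  th <- angleDeg * pi / 180
  R <- matrix(c(cos(th), sin(th), -sin(th), cos(th)), 2, 2)
  sweep(sweep(ring, 2, center) %*% t(R), 2, center, "+")
}

#' Rigid registration of two tissue outlines
#'
#' Brute-force grid search over rotations (about the second outline's
#' centroid) and XY translations maximising the intersection-over-union
#' of the two outlines, computed on a raster. The grid always contains
#' the identity, so the reported IoU never decreases. The consensus
#' outline is the geometric intersection of the aligned outlines (largest
#' connected component), the region subsequently used for comparing
#' consecutive sections.
#'
#' @param outlineA,outlineB \code{MembraneHull} tissue outlines.
#' @param angleStep rotation step (degrees).
#' @param translationStep translation step (micrometres).
#' @param maxAngle half-width of the rotation search (degrees).
#' @param maxTranslation half-width of the translation search
#'   (micrometres).
#' @param resolution raster resolution (micrometres); default
#'   \code{translationStep / 2}.
#' @return list with \code{rotation} (degrees), \code{translation}
#'   (dx, dy in micrometres applied to outline B after rotation),
#'   \code{iouBefore}, \code{iouAfter}, and \code{consensus} (a
#'   \code{MembraneHull}, or NULL with a warning when the best overlap is
#'   empty).
#' @export
registerOutlines <- function(outlineA, outlineB, angleStep = 0.5,
                             translationStep = 25, maxAngle = 15,
                             maxTranslation = 500, resolution = NULL) {
  if (hullArea(outlineA) <= 0 || hullArea(outlineB) <= 0)
    stop("both outlines must have positive area")
  res <- if (is.null(resolution)) translationStep / 2 else resolution
  sPix <- max(1L, round(translationStep / res))
  maxShift <- round(maxTranslation / res)
  va <- outlineA@exterior; vb <- outlineB@exterior
  cb <- ringCentroid(vb)
  pad <- maxTranslation + 2 * res +
    max(dist(rbind(cb, vb)))  # room for any rotation of B
  bbox <- c(min(va[, 1], vb[, 1]) - pad, max(va[, 1], vb[, 1]) + pad,
            min(va[, 2], vb[, 2]) - pad, max(va[, 2], vb[, 2]) + pad)
  rasA <- rasterizeHulls(list(outlineA), res, bbox)
  maskA <- rasA$mask
  areaA <- sum(maskA)
  nx <- nrow(maskA); ny <- ncol(maskA)
  shifts <- seq(-maxShift, maxShift, by = sPix)
  angles <- seq(-maxAngle, maxAngle, by = angleStep)
  angles <- angles[order(abs(angles))]  # identity first
  overlapAt <- function(maskB, sx, sy) {
    ax <- max(1L, 1L + sx):min(nx, nx + sx)
    ay <- max(1L, 1L + sy):min(ny, ny + sy)
    if (length(ax) == 0L || length(ay) == 0L) return(0)
    sum(maskA[ax, ay] & maskB[ax - sx, ay - sy])
  }
  best <- list(iou = -1, angle = 0, sx = 0L, sy = 0L, maskB = NULL)
  iouBefore <- NA_real_
  for (ang in angles) {
    hb <- MembraneHull(rotateRing(vb, ang, cb),
                       holes = lapply(outlineB@holes, rotateRing,
                                      angleDeg = ang, center = cb),
                       marker = outlineB@marker)
    maskB <- rasterizeHulls(list(hb), res, bbox)$mask
    areaB <- sum(maskB)
    for (sx in shifts) for (sy in shifts) {
      inter <- overlapAt(maskB, sx, sy)
      iou <- if (areaA + areaB - inter > 0)
        inter / (areaA + areaB - inter) else 0
      if (ang == 0 && sx == 0L && sy == 0L) iouBefore <- iou
      if (iou > best$iou + 1e-12) {
        best <- list(iou = iou, angle = ang, sx = sx, sy = sy,
                     maskB = maskB)
      }
    }
  }
  interMask <- matrix(FALSE, nx, ny)
  ax <- max(1L, 1L + best$sx):min(nx, nx + best$sx)
  ay <- max(1L, 1L + best$sy):min(ny, ny + best$sy)
  if (length(ax) && length(ay))
    interMask[ax, ay] <- maskA[ax, ay] & best$maskB[ax - best$sx,
                                                    ay - best$sy]
  consensus <- NULL
  if (!any(interMask)) {
    warning("no overlap between outlines: empty consensus")
  } else {
    xs <- rasA$origin[1] + (seq_len(nx) - 0.5) * res
    ys <- rasA$origin[2] + (seq_len(ny) - 0.5) * res
    cl <- grDevices::contourLines(xs, ys, interMask + 0, levels = 0.5)
    if (length(cl)) {
      areas <- vapply(cl, function(cc)
        abs(ringArea(cbind(cc$x, cc$y))), numeric(1))
      cc <- cl[[which.max(areas)]]
      consensus <- MembraneHull(cbind(cc$x, cc$y), marker = "consensus")
    }
  }
  list(rotation = best$angle,
       translation = c(dx = best$sx * res, dy = best$sy * res),
       iouBefore = iouBefore, iouAfter = best$iou,
       consensus = consensus)
}
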