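#' Gaussian kernel density field on a regular grid
#'
#' Isotropic Gaussian KDE without edge correction:
#' \code{value(g) = sum_i (2 pi sigma^2)^-1 exp(-||g - p_i||^2 / (2 sigma^2))},
#' so the field integrates to the point count on grids extending well
#' beyond the points. The default grid uses spacing \code{sigma / 10} and
#' pads the bounding box by \code{4 sigma}, keeping the integration error
#' below 1 percent.
#'
#' @param points n x 2 matrix or \code{CellMap}.
#' @param sigma kernel bandwidth (micrometres).
#' @param grid optional list(origin, spacing, nx, ny); default derived
#'   from the points. Required when \code{points} is empty.
#' @return a \code{DensityField} of kind "intensity".
#' @export
kdeField <- function(points, sigma, grid = NULL) {
  if (sigma <= 0) stop("sigma must be positive")
  xy <- if (is(points, "CellMap")) coords(points) else
    matrix(as.numeric(points), ncol = 2)
  if (nrow(xy) == 0L) {
    if (is.null(grid))
      stop("empty point set requires an explicit grid")
    warning("empty point set: returning a zero field")
  }
  if (is.null(grid)) {
    spacing <- sigma / 10
    pad <- 4 * sigma
    x0 <- min(xy[, 1]) - pad; x1 <- max(xy[, 1]) + pad
    y0 <- min(xy[, 2]) - pad; y1 <- max(xy[, 2]) + pad
    grid <- list(origin = c(x0, y0), spacing = spacing,
                 nx = ceiling((x1 - x0) / spacing) + 1L,
                 ny = ceiling((y1 - y0) / spacing) + 1L)
  }
  gx <- grid$origin[1] + (seq_len(grid$nx) - 1) * grid$spacing
  gy <- grid$origin[2] + (seq_len(grid$ny) - 1) * grid$spacing
  if (nrow(xy) > 0L) {
    ex <- exp(-outer(gx, xy[, 1], "-")^2 / (2 * sigma^2))
    ey <- exp(-outer(gy, xy[, 2], "-")^2 / (2 * sigma^2))
    vals <- (ex %*% t(ey)) / (2 * pi * sigma^2)
  } else {
    vals <- matrix(0, grid$nx, grid$ny)
  }
  new("DensityField", origin = grid$origin, spacing = grid$spacing,
      values = vals, sigma = sigma, kind = "intensity",
      mask = matrix(TRUE, grid$nx, grid$ny),
      points = xy)
}

sameGrid <- function(a, b) {
  isTRUE(all.equal(a@origin, b@origin)) &&
    isTRUE(all.equal(a@spacing, b@spacing)) &&
    identical(dim(a@values), dim(b@values)) &&
    isTRUE(all.equal(a@sigma, b@sigma))
}

# Minimum distance from each grid node to any point.
gridMinDistance <- function(gx, gy, pts) {
  M <- matrix(Inf, length(gx), length(gy))
  for (i in seq_len(nrow(pts))) {
    M <- pmin(M, outer((gx - pts[i, 1])^2, (gy - pts[i, 2])^2, "+"))
  }
  sqrt(M)
}

#' Corrected (ratio) marker density
#'
#' The corrected marker density is the ratio of the marker-positive cell
#' kernel density over the total cell kernel density, evaluated on the
#' shared grid. The ratio is only defined where the total density is
#' informative: nodes with total density below \code{minTotal} or farther
#' than \code{maskRadius} from any cell are masked. When the positive
#' cells are a subset of all cells the ratio lies in [0, 1] (clamped
#' against floating-point round-off).
#'
#' @param posField KDE of marker-positive cells.
#' @param totalField KDE of all cells (same grid and sigma).
#' @param minTotal minimum total density (per um^2) for a defined ratio.
#' @param maskRadius nodes farther than this from every cell are masked;
#'   default \code{2 * sigma}.
#' @return a \code{DensityField} of kind "ratio".
#' @export
correctedDensity <- function(posField, totalField, minTotal = 1e-12,
                             maskRadius = NULL) {
  if (!sameGrid(posField, totalField))
    stop("grid mismatch between positive and total fields")
  if (is.null(maskRadius)) maskRadius <- 2 * totalField@sigma
  g <- gridNodes(totalField)
  mask <- totalField@values >= minTotal
  if (nrow(totalField@points) > 0L && is.finite(maskRadius)) {
    mask <- mask &
      (gridMinDistance(g$x, g$y, totalField@points) <= maskRadius)
  } else if (nrow(totalField@points) == 0L) {
    mask[] <- FALSE
  }
  ratio <- matrix(0, nrow(mask), ncol(mask))
  ratio[mask] <- pmin(1, pmax(0, posField@values[mask] /
                                   totalField@values[mask]))
  new("DensityField", origin = totalField@origin,
      spacing = totalField@spacing, values = ratio,
      sigma = totalField@sigma, kind = "ratio", mask = mask,
      points = totalField@points)
}

#' Sample a density field at cell positions
#'
#' Bilinear interpolation of the field at each cell's coordinates. Cells
#' outside the grid extent, or whose four surrounding nodes include a
#' masked node, are flagged undefined rather than dropped.
#'
#' @param field a \code{DensityField}.
#' @param cells a \code{CellMap} or n x 2 coordinate matrix.
#' @return data.frame with \code{cell_id}, \code{value}, \code{defined}.
#' @export
densityAtCells <- function(field, cells) {
  xy <- if (is(cells, "CellMap")) coords(cells) else
    matrix(as.numeric(cells), ncol = 2)
  ids <- if (is(cells, "CellMap")) cellData(cells)$cell_id else
    as.character(seq_len(nrow(xy)))
  nx <- nrow(field@values); ny <- ncol(field@values)
  fx <- (xy[, 1] - field@origin[1]) / field@spacing + 1
  fy <- (xy[, 2] - field@origin[2]) / field@spacing + 1
  i0 <- floor(fx); j0 <- floor(fy)
  inGrid <- i0 >= 1 & i0 <= nx - 1e-9 & j0 >= 1 & j0 <= ny - 1e-9
  # cells exactly on the far edge snap onto the last node
  i0 <- pmin(pmax(i0, 1), nx - 1); j0 <- pmin(pmax(j0, 1), ny - 1)
  tx <- fx - i0; ty <- fy - j0
  idx <- function(i, j) cbind(i, j)
  v00 <- field@values[idx(i0, j0)]; v10 <- field@values[idx(i0 + 1, j0)]
  v01 <- field@values[idx(i0, j0 + 1)]
  v11 <- field@values[idx(i0 + 1, j0 + 1)]
  val <- (1 - tx) * (1 - ty) * v00 + tx * (1 - ty) * v10 +
    (1 - tx) * ty * v01 + tx * ty * v11
  m00 <- field@mask[idx(i0, j0)]; m10 <- field@mask[idx(i0 + 1, j0)]
  m01 <- field@mask[idx(i0, j0 + 1)]
  m11 <- field@mask[idx(i0 + 1, j0 + 1)]
  defined <- inGrid & m00 & m10 & m01 & m11
  val[!defined] <- NA_real_
  data.frame(cell_id = ids, value = val, defined = defined)
}

#' Pooled equal-count binning of per-cell density values
#'
#' Cells from all samples are pooled, sorted by value (ties broken by
#' stable input order) and split into \code{nBins} contiguous groups
#' whose sizes differ by at most one; when the count is not divisible the
#' lowest-index bins take the extra cell. Bin 1 holds the lowest values.
#' Undefined (NA) values receive an NA bin.
#'
#' @param values pooled per-cell density values (NA for undefined).
#' @param nBins number of bins (the whole-slide procedure uses 20).
#' @return integer vector of bin ids aligned with \code{values}.
#' @export
pooledEqualCountBins <- function(values, nBins = 20) {
  ok <- which(!is.na(values))
  n <- length(ok)
  if (n < nBins)
    stop(sprintf("only %d defined values for %d bins", n, nBins))
  ord <- ok[order(values[ok], seq_along(ok))]
  base <- n %/% nBins
  sizes <- base + as.integer(seq_len(nBins) <= (n %% nBins))
  bins <- rep.int(seq_len(nBins), sizes)
  out <- rep(NA_integer_, length(values))
  out[ord] <- bins
  out
}

#' Bin composition table
#'
#' For each density bin: the number of cells, the mean density, and the
#' fraction of the bin's cells contributed by each sample group; and per
#' bin and group, the phenotype composition of that group's cells.
#'
#' @param binIds integer bin ids from \code{\link{pooledEqualCountBins}}.
#' @param cellMap the pooled \code{CellMap} (same cell order).
#' @param sampleGroups named character vector mapping every sample id to
#'   a group label; an unmapped sample is an error.
#' @param phenotypesOfInterest optional named list mapping an output
#'   label to one or more phenotype labels (e.g.
#'   \code{list(T = c("CD4T", "CD8T"), TAM = "TAM")}); default: every
#'   observed phenotype separately, so fractions per bin and group sum
#'   to 1.
#' @param values optional per-cell density values for the per-bin mean.
#' @return list of class \code{BinTable} with \code{binSummary} and
#'   \code{phenotypeFractions} data.frames and \code{nUndefined}.
#' @export
binComposition <- function(binIds, cellMap, sampleGroups,
                           phenotypesOfInterest = NULL, values = NULL) {
  stopifnot(length(binIds) == nCells(cellMap))
  d <- cellData(cellMap)
  samples <- unique(d$sample_id)
  unknown <- setdiff(samples, names(sampleGroups))
  if (length(unknown))
    stop("unknown group label for sample(s): ",
         paste(unknown, collapse = ", "))
  grp <- unname(sampleGroups[d$sample_id])
  groups <- sort(unique(unname(sampleGroups)))
  keep <- !is.na(binIds)
  nUndefined <- sum(!keep)
  b <- binIds[keep]; g <- grp[keep]; ph <- d$phenotype[keep]
  v <- if (!is.null(values)) values[keep] else NULL
  bins <- sort(unique(b))
  binSummary <- data.frame(bin = bins,
                           n = as.integer(table(factor(b, levels = bins))))
  if (!is.null(v))
    binSummary$mean_density <- as.numeric(
      tapply(v, factor(b, levels = bins), mean))
  for (gg in groups) {
    binSummary[[paste0("frac_", gg)]] <- as.numeric(
      tapply(g == gg, factor(b, levels = bins), mean))
  }
  if (is.null(phenotypesOfInterest)) {
    phenotypesOfInterest <- as.list(sort(unique(ph)))
    names(phenotypesOfInterest) <- sort(unique(ph))
  }
  rows <- list()
  for (bb in bins) for (gg in groups) {
    inCell <- b == bb & g == gg
    ng <- sum(inCell)
    for (pn in names(phenotypesOfInterest)) {
      rows[[length(rows) + 1L]] <- data.frame(
        bin = bb, group = gg, phenotype = pn, n_group = ng,
        fraction = if (ng > 0)
          sum(ph[inCell] %in% phenotypesOfInterest[[pn]]) / ng
        else NA_real_)
    }
  }
  out <- list(binSummary = binSummary,
              phenotypeFractions = do.call(rbind, rows),
              nUndefined = nUndefined)
  class(out) <- "BinTable"
  out
}

#' @export
print.BinTable <- function(x, ...) {
  cat(sprintf("BinTable: %d bins, %d cells (%d undefined excluded)\n",
              nrow(x$binSummary), sum(x$binSummary$n), x$nUndefined))
  print(utils::head(x$binSummary, 5))
  invisible(x)
}
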