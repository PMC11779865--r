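# Row-wise minima of a numeric matrix via max.col (C speed, no copies
# beyond the subset itself).
rowMins <- function(M) {
  M[cbind(seq_len(nrow(M)), max.col(-M, ties.method = "first"))]
}

#' Nearest-neighbour distances between two cell sets
#'
#' For every cell of the from-set, the Euclidean distance to the nearest
#' cell of the to-set. With \code{excludeSelf}, cells sharing a cell id
#' between the two sets are not their own neighbour; coincident distinct
#' cells still count at distance zero.
#'
#' @param fromCells,toCells \code{CellMap}s or n x 2 coordinate matrices.
#' @param excludeSelf drop identical cell ids (or identical row indices
#'   for bare matrices of equal size) from the candidate neighbours.
#' @return numeric vector, one distance (micrometres) per from-cell.
#' @examples
#' a <- CellMap(data.frame(x = 0, y = 0, phenotype = "CD8T"))
#' b <- CellMap(data.frame(x = 3, y = 4, phenotype = "TAM"))
#' nnDistances(a, b)
#' @export
nnDistances <- function(fromCells, toCells, excludeSelf = FALSE) {
  fxy <- if (is(fromCells, "CellMap")) coords(fromCells) else
    matrix(as.numeric(fromCells), ncol = 2)
  txy <- if (is(toCells, "CellMap")) coords(toCells) else
    matrix(as.numeric(toCells), ncol = 2)
  fid <- if (is(fromCells, "CellMap")) cellData(fromCells)$cell_id else NULL
  tid <- if (is(toCells, "CellMap")) cellData(toCells)$cell_id else NULL
  if (nrow(txy) == 0L)
    stop("undefined statistic: to-set is empty")
  D <- crossDistances(fxy, txy)
  if (excludeSelf) {
    if (!is.null(fid) && !is.null(tid)) {
      hit <- outer(fid, tid, "==")
      D[hit] <- Inf
    } else if (nrow(fxy) == nrow(txy)) {
      diag(D) <- Inf
    }
    if (any(!is.finite(rowMins(D))))
      stop("undefined statistic: to-set empty after self-exclusion")
  }
  rowMins(D)
}

crossDistances <- function(a, b) {
  d2 <- outer(rowSums(a^2), rowSums(b^2), "+") - 2 * tcrossprod(a, b)
  sqrt(pmax(d2, 0))
}

# Mean NN distance from from-positions to to-positions given a full
# pairwise distance matrix and a label vector; NA when degenerate.
nnStatFromLabels <- function(D, lab, fromType, toType) {
  rows <- which(lab == fromType)
  cols <- which(lab == toType)
  M <- D[rows, cols, drop = FALSE]
  if (fromType == toType) {
    if (length(cols) < 2L) return(NA_real_)
    M[cbind(seq_along(rows), seq_along(cols))] <- Inf
  }
  mean(rowMins(M))
}

#' Permutation nearest-neighbour z-score for one phenotype pair
#'
#' The observed statistic is the mean distance from each from-type cell
#' to its nearest to-type cell, averaged over all from-type cells in the
#' map. The null is built by randomly reassigning the phenotype labels
#' over all cells of the map (all phenotypes jointly, marginal counts
#' preserved) and recomputing the statistic; the z-score compares the
#' observed value with the null mean and SD. Negative z indicates
#' clustering of the pair, positive z dispersion.
#'
#' In \code{"sampled"} mode \code{nPerm} label reassignments are drawn
#' (the ROI procedure uses 1000, the whole-slide procedure 100); the
#' observed labelling is not added to the null. In \code{"exhaustive"}
#' mode all distinct placements of the from/to labels are enumerated
#' (cells carrying other labels are exchangeable for this statistic), the
#' null SD is the population SD over the enumeration, and the result is
#' seed-independent.
#'
#' @param cellMap a \code{CellMap}.
#' @param fromType,toType phenotype labels.
#' @param nPerm number of sampled permutations (ignored in exhaustive
#'   mode).
#' @param seed RNG seed for sampled mode.
#' @param mode "sampled" or "exhaustive".
#' @return an \code{NNZResult}; \code{undefined} is set (and z is NA)
#'   when the null SD vanishes.
#' @export
permutationNNZ <- function(cellMap, fromType, toType, nPerm = 1000,
                           seed = NULL, mode = c("sampled", "exhaustive")) {
  mode <- match.arg(mode)
  lab <- phenotypes(cellMap)
  for (ty in unique(c(fromType, toType))) {
    if (!any(lab == ty))
      stop(sprintf("missing type: no '%s' cells in the map", ty))
  }
  nf <- sum(lab == fromType); nt <- sum(lab == toType)
  if (fromType == toType && nt < 2L)
    stop("undefined statistic: to-set empty after self-exclusion")
  D <- crossDistances(coords(cellMap), coords(cellMap))
  obs <- nnStatFromLabels(D, lab, fromType, toType)
  if (mode == "sampled") {
    if (nPerm < 2L) stop("sampled mode needs nPerm >= 2")
    null <- withSeed(seed, {
      vapply(seq_len(nPerm), function(k)
        nnStatFromLabels(D, sample(lab), fromType, toType), numeric(1))
    })
    nullMean <- mean(null); nullSd <- sd(null)
    nRealized <- as.integer(nPerm)
  } else {
    null <- exhaustiveNullStats(D, lab, fromType, toType)
    nullMean <- mean(null)
    nullSd <- sqrt(mean((null - nullMean)^2))
    nRealized <- length(null)
  }
  undef <- !is.finite(nullSd) || nullSd <= 1e-12
  new("NNZResult", fromType = fromType, toType = toType,
      nFrom = as.integer(nf), nTo = as.integer(nt),
      observedMeanNN = obs, nullMean = nullMean, nullSd = nullSd,
      z = if (undef) NA_real_ else (obs - nullMean) / nullSd,
      nPerm = nRealized, mode = mode, undefined = undef)
}

# All distinct placements of the from/to labels over the n positions;
# other labels are exchangeable for the NN statistic, so each placement
# carries equal weight. Returns the statistic per placement.
exhaustiveNullStats <- function(D, lab, fromType, toType,
                                maxAssignments = 2e5) {
  n <- length(lab)
  nf <- sum(lab == fromType); nt <- sum(lab == toType)
  if (fromType == toType) {
    total <- choose(n, nf)
    if (total > maxAssignments)
      stop("exhaustive enumeration too large; use sampled mode")
    combs <- utils::combn(n, nf)
    apply(combs, 2, function(rows) {
      M <- D[rows, rows, drop = FALSE]
      diag(M) <- Inf
      mean(rowMins(M))
    })
  } else {
    total <- choose(n, nf) * choose(n - nf, nt)
    if (total > maxAssignments)
      stop("exhaustive enumeration too large; use sampled mode")
    fsets <- utils::combn(n, nf)
    unlist(lapply(seq_len(ncol(fsets)), function(i) {
      rows <- fsets[, i]
      rest <- setdiff(seq_len(n), rows)
      tsets <- utils::combn(rest, nt)
      apply(tsets, 2, function(cols)
        mean(rowMins(D[rows, cols, drop = FALSE])))
    }), use.names = FALSE)
  }
}

#' Nearest-neighbour z-scores for a set of phenotype pairs
#'
#' Runs the permutation z-score for each requested (from, to) pair on a
#' shared set of label reassignments (sampled mode). Pairs whose types
#' are absent from the map are emitted as undefined rows, not dropped.
#'
#' @param cellMap a \code{CellMap}.
#' @param typePairs character vector of \code{"from:to"} pairs, or a
#'   data.frame with columns \code{from} and \code{to}.
#' @param nPerm sampled permutations per pair.
#' @param seed RNG seed.
#' @return tidy data.frame, one row per pair, with columns \code{from},
#'   \code{to}, \code{n_from}, \code{n_to}, \code{observed_mean_nn},
#'   \code{null_mean}, \code{null_sd}, \code{z}, \code{n_perm},
#'   \code{mode}, \code{undefined}.
#' @export
zscoreMatrix <- function(cellMap, typePairs, nPerm = 1000, seed = NULL) {
  pairs <- if (is.data.frame(typePairs)) {
    data.frame(from = as.character(typePairs$from),
               to = as.character(typePairs$to))
  } else {
    sp <- strsplit(typePairs, ":", fixed = TRUE)
    data.frame(from = vapply(sp, `[`, "", 1),
               to = vapply(sp, `[`, "", 2))
  }
  lab <- phenotypes(cellMap)
  n <- length(lab)
  D <- if (n > 0L) crossDistances(coords(cellMap), coords(cellMap)) else NULL
  perms <- if (n > 0L) withSeed(seed, {
    lapply(seq_len(nPerm), function(k) sample(lab))
  }) else list()
  out <- lapply(seq_len(nrow(pairs)), function(i) {
    fromType <- pairs$from[i]; toType <- pairs$to[i]
    nf <- sum(lab == fromType); nt <- sum(lab == toType)
    base <- data.frame(from = fromType, to = toType, n_from = nf,
                       n_to = nt, observed_mean_nn = NA_real_,
                       null_mean = NA_real_, null_sd = NA_real_,
                       z = NA_real_, n_perm = as.integer(nPerm),
                       mode = "sampled", undefined = TRUE)
    degenerate <- nf == 0L || nt == 0L ||
      (fromType == toType && nt < 2L)
    if (degenerate) return(base)
    obs <- nnStatFromLabels(D, lab, fromType, toType)
    null <- vapply(perms, function(p)
      nnStatFromLabels(D, p, fromType, toType), numeric(1))
    nullMean <- mean(null); nullSd <- sd(null)
    base$observed_mean_nn <- obs
    base$null_mean <- nullMean
    base$null_sd <- nullSd
    if (is.finite(nullSd) && nullSd > 1e-12) {
      base$z <- (obs - nullMean) / nullSd
      base$undefined <- FALSE
    }
    base
  })
  do.call(rbind, out)
}

#' Kolmogorov-Smirnov comparison of distances to the nearest vessel
#'
#' Computes the Euclidean distance from every cell centroid to the
#' nearest point of any vessel polygon (zero for cells inside a vessel),
#' splits cells into a marker-positive and a negative group, subsamples
#' each group without replacement to at most \code{maxPerGroup} cells
#' (the whole-slide procedure caps both groups at 2000), and applies a
#' two-sided two-sample KS test to the two distance distributions.
#'
#' @param cellMap a \code{CellMap}.
#' @param vessels list of vessel \code{MembraneHull}s.
#' @param positiveLabel phenotype label(s) forming the positive group.
#' @param maxPerGroup subsampling cap per group (default 2000).
#' @param seed RNG seed for the subsampling.
#' @param negativeLabels optional explicit negative-group labels;
#'   default: all cells not in the positive group.
#' @return a \code{KSResult}.
#' @export
vesselDistanceKS <- function(cellMap, vessels, positiveLabel,
                             maxPerGroup = 2000, seed = NULL,
                             negativeLabels = NULL) {
  if (length(vessels) == 0L) stop("no vessels supplied")
  lab <- phenotypes(cellMap)
  pos <- lab %in% positiveLabel
  neg <- if (is.null(negativeLabels)) !pos else lab %in% negativeLabels
  if (!any(pos)) stop("empty group: no positive cells")
  if (!any(neg)) stop("empty group: no negative cells")
  d <- distanceToHulls(coords(cellMap), vessels)
  dPos <- d[pos]; dNeg <- d[neg]
  sub <- withSeed(seed, {
    list(pos = if (length(dPos) > maxPerGroup)
           sample(dPos, maxPerGroup) else dPos,
         neg = if (length(dNeg) > maxPerGroup)
           sample(dNeg, maxPerGroup) else dNeg)
  })
  kt <- suppressWarnings(ks.test(sub$pos, sub$neg,
                                 alternative = "two.sided"))
  new("KSResult", D = unname(kt$statistic), pValue = kt$p.value,
      nPos = length(sub$pos), nNeg = length(sub$neg),
      medianPos = median(sub$pos), medianNeg = median(sub$neg))
}
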