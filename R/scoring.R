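#' Equal-count expression bins
#'
#' Ranks genes by mean expression across units and splits them into
#' \code{nBins} contiguous equal-count bins (sizes differing by at most
#' one; ties and remainders resolved by stable gene order, extras to the
#' lowest bins). Bin 1 holds the lowest-expressed genes.
#'
#' @param em an \code{ExpressionMatrix}.
#' @param nBins number of bins (the enrichment score uses 30).
#' @param universe optional gene-id filter applied before binning (e.g. a
#'   most-variable-genes restriction).
#' @return integer vector of bin ids named by gene id.
#' @export
expressionBins <- function(em, nBins = 30, universe = NULL) {
  m <- exprValues(em)
  if (!is.null(universe)) {
    missing <- setdiff(universe, rownames(m))
    if (length(missing))
      stop("gene absent from matrix: ", missing[1])
    m <- m[rownames(m) %in% universe, , drop = FALSE]
  }
  ng <- nrow(m)
  if (ng < nBins)
    stop(sprintf("only %d genes for %d bins", ng, nBins))
  means <- rowMeans(m)
  ord <- order(means, seq_len(ng))
  base <- ng %/% nBins
  sizes <- base + as.integer(seq_len(nBins) <= (ng %% nBins))
  bins <- integer(ng)
  bins[ord] <- rep.int(seq_len(nBins), sizes)
  names(bins) <- rownames(m)
  bins
}

#' Bin-matched background gene-set enrichment score
#'
#' For a gene set G, a reference set R is built by binning all genes into
#' \code{nBins} equal-sized bins by expression level and drawing, for
#' every gene of G, \code{nBackgroundPerGene} random genes from that
#' gene's bin (so R is \code{nBackgroundPerGene} times larger than G; the
#' default 100 matches the published procedure). The per-unit score is
#' the difference in average expression between G and R. Draws are
#' without replacement within one target's background when the bin is
#' large enough, with replacement otherwise (flagged); a gene may serve
#' several targets. \code{exhaustive = TRUE} replaces sampling by the
#' full bin, making the background mean the exact bin mean.
#'
#' Scores are computed on the expression values as provided; apply any
#' normalisation (e.g. \code{\link{logTransformCounts}}) beforehand.
#'
#' @param em an \code{ExpressionMatrix}.
#' @param geneSet character vector of gene ids (G).
#' @param nBins number of expression bins (default 30).
#' @param nBackgroundPerGene background genes drawn per target gene
#'   (default 100).
#' @param seed RNG seed for the background draws.
#' @param universe optional gene universe filter applied before binning.
#' @param exhaustive use every gene of the target's bin instead of
#'   sampling.
#' @return list of class \code{EnrichmentResult}: \code{scores} (named
#'   per-unit numeric), \code{geneSet}, \code{nBins},
#'   \code{nBackgroundPerGene}, \code{withReplacement} (per-target flag),
#'   \code{seed}.
#' @export
binMatchedScore <- function(em, geneSet, nBins = 30,
                            nBackgroundPerGene = 100, seed = NULL,
                            universe = NULL, exhaustive = FALSE) {
  if (length(geneSet) == 0L) stop("empty gene set")
  m <- exprValues(em)
  missing <- setdiff(geneSet, rownames(m))
  if (length(missing))
    stop("gene absent from matrix: ", missing[1])
  bins <- expressionBins(em, nBins = nBins, universe = universe)
  if (!all(geneSet %in% names(bins)))
    stop("gene absent from universe: ",
         setdiff(geneSet, names(bins))[1])
  byBin <- split(names(bins), bins)
  unitMeansOfG <- colMeans(m[geneSet, , drop = FALSE])
  withRepl <- logical(length(geneSet))
  refSum <- numeric(ncol(m))
  nRef <- 0L
  draws <- withSeed(seed, {
    lapply(seq_along(geneSet), function(i) {
      pool <- byBin[[as.character(bins[[geneSet[i]]])]]
      if (exhaustive) return(pool)
      if (length(pool) >= nBackgroundPerGene) {
        sample(pool, nBackgroundPerGene, replace = FALSE)
      } else {
        sample(pool, nBackgroundPerGene, replace = TRUE)
      }
    })
  })
  for (i in seq_along(draws)) {
    pool <- byBin[[as.character(bins[[geneSet[i]]])]]
    withRepl[i] <- !exhaustive && length(pool) < nBackgroundPerGene
    refSum <- refSum + colSums(m[draws[[i]], , drop = FALSE])
    nRef <- nRef + length(draws[[i]])
  }
  if (any(withRepl))
    warning(sprintf(
      "%d target(s) in bins smaller than %d: background drawn with replacement",
      sum(withRepl), nBackgroundPerGene))
  scores <- unitMeansOfG - refSum / nRef
  out <- list(scores = scores, geneSet = geneSet, nBins = nBins,
              nBackgroundPerGene = nBackgroundPerGene,
              withReplacement = withRepl, seed = seed)
  class(out) <- "EnrichmentResult"
  out
}

#' @export
print.EnrichmentResult <- function(x, ...) {
  cat(sprintf(
    "EnrichmentResult: %d-gene set, %d units, score range [%.3f, %.3f]\n",
    length(x$geneSet), length(x$scores), min(x$scores), max(x$scores)))
  invisible(x)
}

#' Ordinal GTC abundance category
#'
#' Bins the fraction of gemistocytic tumor cells among malignant cells
#' into the four histology categories: 0 percent, 0-20, 20-40 and above
#' 40 percent. The intervals are right-closed, so a fraction of exactly
#' 0.20 falls in "+".
#'
#' @param fraction GTC fraction(s) in [0, 1].
#' @return factor with levels \code{-}, \code{+}, \code{++}, \code{+++}.
#' @examples
#' gtcCategory(c(0, 0.1, 0.3, 0.5))
#' @export
gtcCategory <- function(fraction) {
  if (anyNA(fraction) || any(fraction < 0 | fraction > 1))
    stop("fraction must lie in [0, 1]")
  lev <- c("-", "+", "++", "+++")
  out <- ifelse(fraction == 0, "-",
                ifelse(fraction <= 0.20, "+",
                       ifelse(fraction <= 0.40, "++", "+++")))
  factor(out, levels = lev, ordered = TRUE)
}

#' Binary GTC class
#'
#' GTC-high versus GTC-low at the WHO-style threshold of about 20
#' percent GTCs among malignant cells; high requires a fraction strictly
#' above the threshold.
#'
#' @param fraction GTC fraction(s) in [0, 1].
#' @param threshold classification threshold (default 0.20).
#' @return character vector of "high"/"low".
#' @examples
#' gtcClass(c(0.05, 0.5))
#' @export
gtcClass <- function(fraction, threshold = 0.20) {
  if (anyNA(fraction) || any(fraction < 0 | fraction > 1))
    stop("fraction must lie in [0, 1]")
  ifelse(fraction > threshold, "high", "low")
}
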