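#' Default phenotype pairs for the z-score panel
#'
#' Within- and between-type pairs for lymphocytes and TAMs, the panel
#' summarised per ROI.
#' @return character vector of "from:to" pairs.
#' @export
defaultTypePairs <- function() {
  c("CD4T:CD4T", "CD8T:CD8T", "CD4T:CD8T", "CD8T:CD4T",
    "TAM:TAM", "TAM:CD4T", "TAM:CD8T")
}

#' Configuration for the per-ROI analysis pipeline
#'
#' @param nPerPhenotype simulated ROIs per tissue phenotype (cuff,
#'   stromal_T, absent).
#' @param tissue a \code{\link{tissueConfig}} used as the ROI simulation
#'   preset.
#' @param pairs "from:to" phenotype pairs for the z-score panel.
#' @param nPerm permutations per ROI (the ROI procedure uses 1000).
#' @param tLabels phenotype labels counted as T cells.
#' @param seed master seed.
#' @return config list.
#' @export
roiAnalysisConfig <- function(nPerPhenotype = 10,
                              tissue = tissueConfig(),
                              pairs = defaultTypePairs(),
                              nPerm = 1000,
                              tLabels = tCellLabels(),
                              seed = 1L) {
  list(nPerPhenotype = as.integer(nPerPhenotype), tissue = tissue,
       pairs = pairs, nPerm = as.integer(nPerm), tLabels = tLabels,
       seed = as.integer(seed))
}

#' Run the per-ROI analysis pipeline
#'
#' Simulates a cohort of 670 x 502 um ROIs (equal numbers of cuff,
#' stromal-T and T-absent tissue phenotypes), then per ROI: phenotype
#' counts and pseudo-count log counts, the permutation z-score panel,
#' cuff detection, tissue-phenotype calling and the GTC category from
#' the simulated malignant-cell composition. Group comparisons (z-scores
#' across tissue phenotypes, Wilcoxon rank-sum with BH adjustment over
#' the panel) complete the report. Deterministic given the config seed.
#'
#' @param config from \code{\link{roiAnalysisConfig}}.
#' @return list of class \code{RunReport}: \code{roiTable},
#'   \code{cuffTable}, \code{comparisons}, \code{metadata}.
#' @export
runROIAnalysis <- function(config) {
  phenos <- c("cuff", "stromal_T", "absent")
  nROIs <- config$nPerPhenotype * length(phenos)
  if (nROIs == 0L) stop("no ROIs")
  vocab <- phenotypeVocabulary()
  rows <- list(); cuffRows <- list()
  idx <- 0L
  for (tp in phenos) for (k in seq_len(config$nPerPhenotype)) {
    idx <- idx + 1L
    roiId <- sprintf("roi_%03d", idx)
    tcfg <- config$tissue
    tcfg$seed <- stageSeed(config$seed, paste0("roi_", idx))
    class(tcfg) <- "TissueConfig"
    sim <- simulateROI(tcfg, phenotype = tp)
    counts <- table(factor(phenotypes(sim$cells), levels = vocab))
    logCounts <- logTransformCounts(as.numeric(counts))
    zs <- zscoreMatrix(sim$cells, config$pairs, nPerm = config$nPerm,
                       seed = stageSeed(config$seed,
                                        paste0("perm_", idx)))
    cuffs <- detectCuffs(sim$cells, sim$membranes,
                         tLabels = config$tLabels)
    call <- classifyROIPhenotype(sim$cells, cuffs,
                                 tLabels = config$tLabels)
    nMalig <- counts[["TumorCell"]] + counts[["GTC"]]
    gtcFrac <- if (nMalig > 0) counts[["GTC"]] / nMalig else 0
    row <- data.frame(roi_id = roiId, truth_phenotype = tp,
                      tissue_phenotype = call,
                      n_cuffs = nrow(cuffs),
                      gtc_fraction = gtcFrac,
                      gtc_category = as.character(gtcCategory(gtcFrac)),
                      gtc_class = gtcClass(gtcFrac))
    for (i in seq_along(vocab)) {
      row[[paste0("count_", vocab[i])]] <- as.integer(counts[[i]])
      row[[paste0("logcount_", vocab[i])]] <- logCounts[i]
    }
    for (i in seq_len(nrow(zs)))
      row[[paste0("z_", zs$from[i], "_to_", zs$to[i])]] <- zs$z[i]
    rows[[idx]] <- row
    if (nrow(cuffs)) {
      cuffs$members <- NULL
      cuffs$roi_id <- roiId
      cuffRows[[length(cuffRows) + 1L]] <- cuffs
    }
  }
  roiTable <- do.call(rbind, rows)
  cuffTable <- if (length(cuffRows)) do.call(rbind, cuffRows) else
    data.frame(hull_id = integer(0), t_cell_count = integer(0),
               area = numeric(0), equivalent_radius = numeric(0),
               size_class = character(0), roi_id = character(0))
  # declared family: every z column contrasted cuff vs stromal_T
  zcols <- grep("^z_", names(roiTable), value = TRUE)
  comp <- list()
  for (zc in zcols) {
    sub <- roiTable[roiTable$tissue_phenotype %in% c("cuff", "stromal_T") &
                    !is.na(roiTable[[zc]]), ]
    if (length(unique(sub$tissue_phenotype)) == 2L) {
      cg <- compareGroups(sub[[zc]], sub$tissue_phenotype,
                          test = "ranksum", adjust = FALSE)
      cg$contrast <- zc
      comp[[length(comp) + 1L]] <- cg
    }
  }
  comparisons <- if (length(comp)) {
    cc <- do.call(rbind, comp)
    cc$p_adj <- p.adjust(cc$p, method = "BH")
    cc
  } else NULL
  out <- list(roiTable = roiTable, cuffTable = cuffTable,
              comparisons = comparisons,
              metadata = list(seed = config$seed,
                              config_hash = objectHash(config),
                              n_rois = nROIs,
                              version = as.character(
                                utils::packageVersion("perivasc"))))
  class(out) <- "RunReport"
  out
}

#' Two-sided group comparisons with BH adjustment
#'
#' All pairwise contrasts between group levels, using the Wilcoxon
#' rank-sum test (exact for small tie-free samples), the two-sample KS
#' test, or a chi-squared test on the value-by-group table. P-values are
#' Benjamini-Hochberg adjusted across the contrasts of the call (one
#' declared family).
#'
#' @param values observations (numeric; categorical for chisq).
#' @param groups group labels, same length.
#' @param test "ranksum", "ks" or "chisq".
#' @param adjust apply BH across the returned rows (default TRUE).
#' @return data.frame with one row per contrast: \code{group1},
#'   \code{group2}, \code{test}, \code{statistic}, \code{p},
#'   \code{p_adj}, \code{n1}, \code{n2}, \code{flagged} (degenerate
#'   contrast, statistics NA).
#' @examples
#' compareGroups(c(1, 2, 3, 4, 5, 6), rep(c("a", "b"), each = 3))
#' @export
compareGroups <- function(values, groups,
                          test = c("ranksum", "ks", "chisq"),
                          adjust = TRUE) {
  test <- match.arg(test)
  stopifnot(length(values) == length(groups))
  groups <- as.character(groups)
  lev <- unique(groups)
  if (length(lev) < 2L) stop("need at least two groups")
  pairs <- utils::combn(lev, 2)
  rows <- lapply(seq_len(ncol(pairs)), function(i) {
    a <- pairs[1, i]; b <- pairs[2, i]
    x <- values[groups == a]; y <- values[groups == b]
    row <- data.frame(group1 = a, group2 = b, test = test,
                      statistic = NA_real_, p = NA_real_,
                      n1 = length(x), n2 = length(y), flagged = TRUE)
    if (length(x) == 0L || length(y) == 0L) return(row)
    res <- tryCatch(switch(test,
      ranksum = suppressWarnings(
        wilcox.test(x, y, alternative = "two.sided")),
      ks = suppressWarnings(
        ks.test(x, y, alternative = "two.sided")),
      chisq = suppressWarnings(
        stats::chisq.test(table(c(x, y), rep(c(a, b),
                                             c(length(x), length(y))))))),
      error = function(e) NULL)
    if (!is.null(res) && is.finite(res$p.value)) {
      row$statistic <- unname(res$statistic)
      row$p <- res$p.value
      row$flagged <- FALSE
    }
    row
  })
  out <- do.call(rbind, rows)
  out$p_adj <- if (adjust) p.adjust(out$p, method = "BH") else NA_real_
  out
}

#' Configuration for the whole-slide analysis pipeline
#'
#' Two simulation presets mirror the published contrast: GTC-high
#' samples carry the perivascular GTC gradient, TAM coupling and cuff T
#' cells; GTC-low samples have a flat, sparse GTC field, no coupling and
#' only stromal T cells.
#'
#' @param nHigh,nLow number of samples per group.
#' @param highTissue,lowTissue \code{\link{tissueConfig}} presets.
#' @param positiveLabel marker-positive phenotype for the corrected
#'   density (GTCs stand in for the CD44-positive population).
#' @param sigma KDE bandwidth (micrometres; the whole-slide procedure
#'   uses 500).
#' @param nBins equal-count density bins (default 20).
#' @param tLabels labels counted as T cells.
#' @param seed master seed.
#' @return config list.
#' @export
wholeslideConfig <- function(nHigh = 8, nLow = 6,
                             highTissue = tissueConfig(),
                             lowTissue = tissueConfig(
                               gtcIntensity = 40, gtcDecay = Inf,
                               cuffTPerVessel = 0, tamCoupling = 0),
                             positiveLabel = "GTC", sigma = 500,
                             nBins = 20, tLabels = tCellLabels(),
                             seed = 1L) {
  list(nHigh = as.integer(nHigh), nLow = as.integer(nLow),
       highTissue = highTissue, lowTissue = lowTissue,
       positiveLabel = positiveLabel, sigma = sigma,
       nBins = as.integer(nBins), tLabels = tLabels,
       seed = as.integer(seed))
}

#' Run the whole-slide corrected-density analysis
#'
#' Per sample: simulate a tissue section, compute the marker-positive
#' and total KDE fields with the sample's own grid, form the corrected
#' (ratio) density and sample it at every cell. Per-cell values from all
#' samples are pooled into equal-count bins; the bin composition by
#' sample group and phenotype, and per-sample cuff statistics, form the
#' report.
#'
#' @param config from \code{\link{wholeslideConfig}}.
#' @return list of class \code{RunReport}: \code{binTable} (a
#'   \code{BinTable}), \code{perCell}, \code{cuffTable},
#'   \code{sampleGroups}, \code{metadata}.
#' @export
runWholeslideAnalysis <- function(config) {
  samples <- c(sprintf("high_%d", seq_len(config$nHigh)),
               sprintf("low_%d", seq_len(config$nLow)))
  groupOf <- setNames(rep(c("high", "low"),
                          c(config$nHigh, config$nLow)), samples)
  allCells <- list(); allValues <- list(); cuffRows <- list()
  for (s in samples) {
    tcfg <- if (groupOf[[s]] == "high") config$highTissue else
      config$lowTissue
    tcfg$seed <- stageSeed(config$seed, s)
    class(tcfg) <- "TissueConfig"
    sim <- simulateTissue(tcfg)
    d <- cellData(sim$cells)
    if (nrow(d) == 0L) next
    d$sample_id <- s
    d$cell_id <- paste(s, d$cell_id, sep = ":")
    cm <- CellMap(d)
    total <- kdeField(cm, sigma = config$sigma)
    posSel <- phenotypes(cm) %in% config$positiveLabel
    grid <- list(origin = total@origin, spacing = total@spacing,
                 nx = nrow(total@values), ny = ncol(total@values))
    pos <- suppressWarnings(
      kdeField(coords(cm)[posSel, , drop = FALSE],
               sigma = config$sigma, grid = grid))
    ratio <- correctedDensity(pos, total)
    dv <- densityAtCells(ratio, cm)
    allCells[[s]] <- d
    allValues[[s]] <- dv$value
    cuffs <- detectCuffs(cm, sim$membranes, tLabels = config$tLabels)
    if (nrow(cuffs)) {
      cuffs$members <- NULL
      cuffs$sample_id <- s
      cuffRows[[length(cuffRows) + 1L]] <- cuffs
    }
  }
  pooled <- CellMap(do.call(rbind, allCells))
  values <- unlist(allValues, use.names = FALSE)
  bins <- pooledEqualCountBins(values, nBins = config$nBins)
  binTable <- binComposition(
    bins, pooled, sampleGroups = groupOf,
    phenotypesOfInterest = list(T = config$tLabels, TAM = "TAM",
                                GTC = "GTC"),
    values = values)
  perCell <- data.frame(cell_id = cellData(pooled)$cell_id,
                        sample_id = sampleIds(pooled),
                        value = values, bin = bins)
  cuffTable <- if (length(cuffRows)) do.call(rbind, cuffRows) else NULL
  out <- list(binTable = binTable, perCell = perCell,
              cuffTable = cuffTable, sampleGroups = groupOf,
              metadata = list(seed = config$seed,
                              config_hash = objectHash(config),
                              n_samples = length(samples),
                              version = as.character(
                                utils::packageVersion("perivasc"))))
  class(out) <- "RunReport"
  out
}

#' @export
print.RunReport <- function(x, ...) {
  if (!is.null(x$roiTable)) {
    cat(sprintf("RunReport (per-ROI): %d ROIs, %d cuffs\n",
                nrow(x$roiTable), nrow(x$cuffTable)))
    print(table(x$roiTable$tissue_phenotype))
  } else {
    cat(sprintf("RunReport (whole-slide): %d samples, %d cells\n",
                x$metadata$n_samples, nrow(x$perCell)))
  }
  invisible(x)
}
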