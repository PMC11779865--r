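#' Default phenotype vocabulary
#'
#' The phenotype labels recognised by default throughout the package:
#' bulk tumor cells, gemistocytic tumor cells (GTC), tumor-associated
#' macrophages/microglia (TAM), T helper and cytotoxic T cells, B cells
#' and a catch-all class. Unknown labels encountered on input are mapped
#' to \code{"Other"} with a warning.
#'
#' @return character vector of labels.
#' @export
phenotypeVocabulary <- function() {
  c("TumorCell", "GTC", "TAM", "CD4T", "CD8T", "BCell", "Other")
}

#' Default T cell labels
#'
#' Phenotype labels counted as T cells in cuff detection and tissue
#' phenotype calling.
#' @return character vector.
#' @export
tCellLabels <- function() c("CD4T", "CD8T")

#' CellMap: a phenotyped 2-D point set
#'
#' The central container for spatial analyses: one row per cell with
#' coordinates in micrometres, a phenotype label drawn from a declared
#' vocabulary, and sample/ROI identifiers. All spatial statistics in the
#' package consume a \code{CellMap}.
#'
#' @slot cells data.frame with columns \code{cell_id}, \code{x}, \code{y}
#'   (micrometres), \code{phenotype}, \code{sample_id}, \code{roi_id}.
#' @slot vocabulary declared phenotype labels.
#' @slot provenance list recording source path and the coordinate scale
#'   applied on ingest (applied exactly once).
#' @export
setClass("CellMap", slots = c(
  cells = "data.frame",
  vocabulary = "character",
  provenance = "list"
))

setValidity("CellMap", function(object) {
  d <- object@cells
  need <- c("cell_id", "x", "y", "phenotype", "sample_id", "roi_id")
  if (!all(need %in% names(d)))
    return(paste("cells must have columns:", paste(need, collapse = ", ")))
  if (nrow(d) > 0L) {
    if (anyDuplicated(d$cell_id)) return("cell_id values must be unique")
    if (!all(is.finite(d$x)) || !all(is.finite(d$y)))
      return("coordinates must be finite")
    if (!all(d$phenotype %in% object@vocabulary))
      return("phenotype labels outside the declared vocabulary")
  }
  TRUE
})

#' Construct a CellMap
#'
#' @param cells data.frame with at least \code{x}, \code{y},
#'   \code{phenotype}; \code{cell_id}, \code{sample_id}, \code{roi_id}
#'   are filled in when absent. Coordinates are in micrometres.
#' @param vocabulary declared phenotype labels; labels outside it are
#'   remapped to \code{"Other"} with a warning.
#' @param provenance free-form list (source path, coordinate scale).
#' @return a \code{CellMap}.
#' @examples
#' cm <- CellMap(data.frame(x = c(0, 10), y = c(0, 5),
#'                          phenotype = c("CD8T", "TAM")))
#' nCells(cm)
#' @export
CellMap <- function(cells, vocabulary = phenotypeVocabulary(),
                    provenance = list()) {
  cells <- as.data.frame(cells)
  if (nrow(cells) == 0L && !all(c("x", "y", "phenotype") %in% names(cells))) {
    cells <- data.frame(x = numeric(0), y = numeric(0),
                        phenotype = character(0))
  }
  if (!all(c("x", "y", "phenotype") %in% names(cells)))
    stop("'cells' must contain columns x, y, phenotype")
  if (is.null(cells$cell_id))
    cells$cell_id <- if (nrow(cells)) sprintf("cell_%d", seq_len(nrow(cells))) else character(0)
  if (is.null(cells$sample_id)) cells$sample_id <- rep("sample_1", nrow(cells))
  if (is.null(cells$roi_id)) cells$roi_id <- rep(NA_character_, nrow(cells))
  cells$cell_id <- as.character(cells$cell_id)
  cells$sample_id <- as.character(cells$sample_id)
  cells$roi_id <- as.character(cells$roi_id)
  cells$phenotype <- as.character(cells$phenotype)
  unknown <- !(cells$phenotype %in% vocabulary)
  if (any(unknown)) {
    warning(sprintf("%d cells with phenotype outside the vocabulary mapped to 'Other'",
                    sum(unknown)))
    if (!("Other" %in% vocabulary)) vocabulary <- c(vocabulary, "Other")
    cells$phenotype[unknown] <- "Other"
  }
  rownames(cells) <- NULL
  keep <- c("cell_id", "x", "y", "phenotype", "sample_id", "roi_id")
  new("CellMap", cells = cells[, keep], vocabulary = vocabulary,
      provenance = provenance)
}

#' MembraneHull: a closed polygon, possibly with holes
#'
#' Delimits a parenchymal membrane region (LAMA2), a vessel (CD31) or a
#' whole-tissue outline. Rings are stored open (the closing edge from the
#' last to the first vertex is implicit); containment uses the even-odd
#' rule with boundary points counted as contained.
#'
#' @slot exterior n x 2 numeric matrix of vertices (micrometres).
#' @slot holes list of interior rings, same format.
#' @slot marker categorical marker label, e.g. "LAMA2", "CD31",
#'   "tissue-outline".
#' @export
setClass("MembraneHull", slots = c(
  exterior = "matrix",
  holes = "list",
  marker = "character"
))

setValidity("MembraneHull", function(object) {
  ex <- object@exterior
  if (!is.numeric(ex) || ncol(ex) != 2L || nrow(ex) < 3L)
    return("exterior must be an n x 2 numeric matrix with n >= 3")
  if (!all(is.finite(ex))) return("exterior vertices must be finite")
  if (abs(ringArea(ex)) <= 0) return("exterior ring has zero area")
  for (h in object@holes) {
    if (!is.numeric(h) || ncol(h) != 2L || nrow(h) < 3L)
      return("each hole must be an n x 2 numeric matrix with n >= 3")
  }
  TRUE
})

#' Construct a MembraneHull
#'
#' @param exterior n x 2 matrix of exterior-ring vertices (micrometres); a
#'   repeated closing vertex is dropped.
#' @param holes list of interior rings.
#' @param marker marker label.
#' @return a \code{MembraneHull}.
#' @examples
#' sq <- MembraneHull(cbind(c(0, 100, 100, 0), c(0, 0, 100, 100)))
#' hullArea(sq)
#' @export
MembraneHull <- function(exterior, holes = list(), marker = "tissue-outline") {
  exterior <- dropClosingVertex(as.matrix(exterior))
  holes <- lapply(holes, function(h) dropClosingVertex(as.matrix(h)))
  new("MembraneHull", exterior = exterior, holes = holes, marker = marker)
}

dropClosingVertex <- function(ring) {
  ring <- unname(ring)
  storage.mode(ring) <- "double"
  n <- nrow(ring)
  if (n > 1L && all(ring[1L, ] == ring[n, ])) ring <- ring[-n, , drop = FALSE]
  ring
}

#' ExpressionMatrix: genes x units numeric matrix
#'
#' Holds raw counts or normalised expression for cells or samples, the
#' input to the bin-matched enrichment score.
#'
#' @slot values numeric matrix, genes as rows, with unique dimnames.
#' @slot valueKind "raw_count" or "normalized".
#' @export
setClass("ExpressionMatrix", slots = c(
  values = "matrix",
  valueKind = "character"
))

setValidity("ExpressionMatrix", function(object) {
  v <- object@values
  if (!is.numeric(v)) return("values must be numeric")
  if (is.null(rownames(v)) || is.null(colnames(v)))
    return("values must have gene (row) and unit (column) names")
  if (anyDuplicated(rownames(v))) return("duplicate gene ids")
  if (anyDuplicated(colnames(v))) return("duplicate unit ids")
  if (anyNA(v)) return("values contain NA")
  if (any(v < 0)) return("values must be non-negative")
  if (!object@valueKind %in% c("raw_count", "normalized"))
    return("valueKind must be 'raw_count' or 'normalized'")
  TRUE
})

#' Construct an ExpressionMatrix
#' @param values numeric matrix with gene row names and unit column names.
#' @param valueKind "raw_count" or "normalized".
#' @return an \code{ExpressionMatrix}.
#' @export
ExpressionMatrix <- function(values, valueKind = c("raw_count", "normalized")) {
  valueKind <- match.arg(valueKind)
  values <- as.matrix(values)
  storage.mode(values) <- "double"
  new("ExpressionMatrix", values = values, valueKind = valueKind)
}

#' DensityField: a gridded kernel density or density-ratio field
#'
#' Regular grid of values with origin and spacing in micrometres. For
#' \code{kind = "intensity"} the values are a Gaussian kernel density sum
#' (per square micrometre); for \code{kind = "ratio"} they are a corrected
#' marker density in [0, 1] with a mask marking where the ratio is defined.
#'
#' @slot origin numeric(2): x/y of the first grid node (micrometres).
#' @slot spacing grid spacing (micrometres).
#' @slot values nx x ny matrix; \code{values[i, j]} sits at
#'   \code{origin + (c(i, j) - 1) * spacing}.
#' @slot sigma kernel bandwidth (micrometres).
#' @slot kind "intensity" or "ratio".
#' @slot mask logical matrix, TRUE where the value is defined.
#' @slot points the source points (used for distance-based masking).
#' @export
setClass("DensityField", slots = c(
  origin = "numeric",
  spacing = "numeric",
  values = "matrix",
  sigma = "numeric",
  kind = "character",
  mask = "matrix",
  points = "matrix"
))

setValidity("DensityField", function(object) {
  if (length(object@origin) != 2L) return("origin must be numeric(2)")
  if (object@spacing <= 0) return("spacing must be positive")
  if (object@sigma <= 0) return("sigma must be positive")
  if (!object@kind %in% c("intensity", "ratio"))
    return("kind must be 'intensity' or 'ratio'")
  if (!identical(dim(object@mask), dim(object@values)))
    return("mask and values dimensions differ")
  v <- object@values[object@mask]
  if (length(v) && any(v < 0)) return("density values must be non-negative")
  if (object@kind == "ratio" && length(v) && any(v > 1 + 1e-9))
    return("ratio values must lie in [0, 1] where unmasked")
  TRUE
})

#' NNZResult: permutation nearest-neighbour z-score
#'
#' Result of comparing the observed mean nearest-neighbour distance from
#' one phenotype to another against a null built by randomly reassigning
#' phenotype labels over all cells of the map. Negative z means the two
#' phenotypes sit closer than expected (clustering); positive z means
#' dispersion.
#'
#' @slot fromType,toType phenotype labels.
#' @slot nFrom,nTo cell counts per type.
#' @slot observedMeanNN observed mean NN distance (micrometres).
#' @slot nullMean,nullSd permutation-null mean and SD (micrometres).
#' @slot z z-score; NA when undefined.
#' @slot nPerm number of permutations (sampled mode) or enumerated
#'   assignments (exhaustive mode).
#' @slot mode "sampled" or "exhaustive".
#' @slot undefined TRUE when the statistic could not be formed (e.g. the
#'   null SD is zero or a type is absent).
#' @export
setClass("NNZResult", slots = c(
  fromType = "character", toType = "character",
  nFrom = "integer", nTo = "integer",
  observedMeanNN = "numeric", nullMean = "numeric", nullSd = "numeric",
  z = "numeric", nPerm = "integer", mode = "character",
  undefined = "logical"
))

#' KSResult: two-sample Kolmogorov-Smirnov comparison of vessel distances
#'
#' @slot D KS statistic in [0, 1].
#' @slot pValue two-sided p-value.
#' @slot nPos,nNeg realised group sizes after subsampling.
#' @slot medianPos,medianNeg group medians (micrometres).
#' @export
setClass("KSResult", slots = c(
  D = "numeric", pValue = "numeric",
  nPos = "integer", nNeg = "integer",
  medianPos = "numeric", medianNeg = "numeric"
))
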