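#' Read a phenotyped cell table
#'
#' Reads a delimited text export (TSV or CSV, sniffed from the header
#' line) into a \code{CellMap}. Mandatory columns are \code{x}, \code{y}
#' and \code{phenotype} (after applying \code{columnMap}); \code{cell_id},
#' \code{sample_id} and \code{roi_id} are optional. Coordinates are
#' multiplied by \code{coordScale} exactly once on ingest, so pixel
#' exports at 0.5 um/px become micrometres with \code{coordScale = 0.5}.
#' Row order is preserved.
#'
#' @param path delimited text file with a header.
#' @param columnMap named character vector mapping required names to file
#'   column names, e.g. \code{c(x = "Centroid.X", phenotype = "Class")}.
#' @param coordScale micrometres per input coordinate unit (default 1).
#' @param vocabulary declared phenotype vocabulary.
#' @return a \code{CellMap} with provenance recording path and scale.
#' @examples
#' tf <- tempfile(fileext = ".tsv")
#' write.table(data.frame(x = 1:3, y = 4:6, phenotype = "CD8T"),
#'             tf, sep = "\t", row.names = FALSE, quote = FALSE)
#' nCells(readCellTable(tf))
#' @export
readCellTable <- function(path, columnMap = NULL, coordScale = 1,
                          vocabulary = phenotypeVocabulary()) {
  if (!file.exists(path)) stop("file not found: ", path)
  header <- readLines(path, n = 1L)
  sep <- if (grepl("\t", header)) "\t" else ","
  d <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                  check.names = FALSE, colClasses = NA)
  for (std in names(columnMap)) {
    src <- columnMap[[std]]
    if (!src %in% names(d))
      stop(sprintf("format error: mapped column '%s' (for '%s') not found",
                   src, std))
    names(d)[names(d) == src] <- std
  }
  for (col in c("x", "y", "phenotype")) {
    if (!col %in% names(d))
      stop(sprintf("format error: missing mandatory column '%s'", col))
  }
  for (col in c("x", "y")) {
    v <- d[[col]]
    if (!is.numeric(v)) {
      num <- suppressWarnings(as.numeric(v))
      bad <- which(is.na(num) & !is.na(v))
      if (length(bad))
        stop(sprintf("parse error: non-numeric %s coordinate at row %d",
                     col, bad[1]))
      v <- num
    }
    if (anyNA(v)) stop(sprintf("parse error: missing %s coordinate", col))
    d[[col]] <- v * coordScale
  }
  CellMap(d, vocabulary = vocabulary,
          provenance = list(source = path, coord_scale = coordScale,
                            md5 = unname(tools::md5sum(path))))
}

#' Write a cell table
#'
#' Writes a \code{CellMap} as TSV with full coordinate precision, so that
#' a write/read round trip reproduces coordinates to well below 1e-9 um.
#'
#' @param cellMap a \code{CellMap}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeCellTable <- function(cellMap, path) {
  d <- cellData(cellMap)
  d$x <- sprintf("%.17g", d$x)
  d$y <- sprintf("%.17g", d$y)
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read an expression matrix
#'
#' Dense layout: delimited text with genes as rows, the first column
#' holding gene ids and the header holding unit ids. Triplet layout: a
#' MatrixMarket file plus sidecar text files listing gene ids (rows) and
#' unit ids (columns), one per line; missing entries are zero. Both
#' layouts with the same content yield identical matrices.
#'
#' @param path matrix file.
#' @param layout "dense" or "triplet".
#' @param genesPath,unitsPath sidecar id files for the triplet layout
#'   (default \code{<path>.genes} / \code{<path>.units}).
#' @param valueKind "raw_count" or "normalized".
#' @return an \code{ExpressionMatrix}.
#' @export
readExpression <- function(path, layout = c("dense", "triplet"),
                           genesPath = paste0(path, ".genes"),
                           unitsPath = paste0(path, ".units"),
                           valueKind = c("raw_count", "normalized")) {
  layout <- match.arg(layout)
  valueKind <- match.arg(valueKind)
  if (!file.exists(path)) stop("file not found: ", path)
  if (layout == "dense") {
    header <- readLines(path, n = 1L)
    sep <- if (grepl("\t", header)) "\t" else ","
    d <- read.delim(path, sep = sep, stringsAsFactors = FALSE,
                    check.names = FALSE)
    genes <- as.character(d[[1]])
    if (anyDuplicated(genes))
      stop("duplicate gene id: ", genes[duplicated(genes)][1])
    m <- as.matrix(d[, -1, drop = FALSE])
    if (!is.numeric(m)) stop("non-numeric expression values")
    rownames(m) <- genes
  } else {
    if (!file.exists(genesPath)) stop("sidecar not found: ", genesPath)
    if (!file.exists(unitsPath)) stop("sidecar not found: ", unitsPath)
    genes <- readLines(genesPath)
    units <- readLines(unitsPath)
    if (anyDuplicated(genes))
      stop("duplicate gene id: ", genes[duplicated(genes)][1])
    if (anyDuplicated(units))
      stop("duplicate unit id: ", units[duplicated(units)][1])
    sm <- Matrix::readMM(path)
    if (nrow(sm) != length(genes) || ncol(sm) != length(units))
      stop(sprintf(
        "dimension mismatch: matrix %d x %d vs %d genes, %d units",
        nrow(sm), ncol(sm), length(genes), length(units)))
    m <- as.matrix(sm)
    dimnames(m) <- list(genes, units)
  }
  ExpressionMatrix(m, valueKind = valueKind)
}

#' Write an expression matrix as dense TSV
#'
#' @param em an \code{ExpressionMatrix}.
#' @param path output file.
#' @return invisibly, \code{path}.
#' @export
writeExpression <- function(em, path) {
  m <- exprValues(em)
  d <- data.frame(gene_id = rownames(m), m, check.names = FALSE)
  write.table(d, path, sep = "\t", row.names = FALSE, quote = FALSE)
  invisible(path)
}
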