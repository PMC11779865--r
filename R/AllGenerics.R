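#' @name perivasc-accessors
#' @title Accessors for perivasc classes
#' @description Accessor generics for the core containers.
#' @param x an object.
#' @param ... passed on to methods.
NULL

#' @rdname perivasc-accessors
#' @export
setGeneric("cellData", function(x, ...) standardGeneric("cellData"))

#' @rdname perivasc-accessors
#' @export
setGeneric("nCells", function(x, ...) standardGeneric("nCells"))

#' @rdname perivasc-accessors
#' @export
setGeneric("coords", function(x, ...) standardGeneric("coords"))

#' @rdname perivasc-accessors
#' @export
setGeneric("phenotypes", function(x, ...) standardGeneric("phenotypes"))

#' @rdname perivasc-accessors
#' @export
setGeneric("sampleIds", function(x, ...) standardGeneric("sampleIds"))

#' @rdname perivasc-accessors
#' @export
setGeneric("hullArea", function(x, ...) standardGeneric("hullArea"))

#' @rdname perivasc-accessors
#' @export
setGeneric("marker", function(x, ...) standardGeneric("marker"))

#' @rdname perivasc-accessors
#' @export
setGeneric("exprValues", function(x, ...) standardGeneric("exprValues"))

#' @rdname perivasc-accessors
#' @export
setGeneric("geneIds", function(x, ...) standardGeneric("geneIds"))

#' @rdname perivasc-accessors
#' @export
setGeneric("unitIds", function(x, ...) standardGeneric("unitIds"))

#' @rdname perivasc-accessors
#' @export
setGeneric("fieldValues", function(x, ...) standardGeneric("fieldValues"))

#' @rdname perivasc-accessors
#' @export
setGeneric("fieldMask", function(x, ...) standardGeneric("fieldMask"))

#' @rdname perivasc-accessors
#' @export
setGeneric("gridNodes", function(x, ...) standardGeneric("gridNodes"))

#' @rdname perivasc-accessors
#' @export
setMethod("cellData", "CellMap", function(x, ...) x@cells)

#' @rdname perivasc-accessors
#' @export
setMethod("nCells", "CellMap", function(x, ...) nrow(x@cells))

#' @rdname perivasc-accessors
#' @export
setMethod("coords", "CellMap", function(x, ...)
  cbind(x = x@cells$x, y = x@cells$y))

#' @rdname perivasc-accessors
#' @export
setMethod("phenotypes", "CellMap", function(x, ...) x@cells$phenotype)

#' @rdname perivasc-accessors
#' @export
setMethod("sampleIds", "CellMap", function(x, ...) x@cells$sample_id)

#' Subset a CellMap by row index or logical vector
#' @param x a CellMap.
#' @param i indices of cells to keep.
#' @param j,drop ignored.
#' @param ... ignored.
#' @export
setMethod("[", "CellMap", function(x, i, j, ..., drop = FALSE) {
  new("CellMap", cells = x@cells[i, , drop = FALSE],
      vocabulary = x@vocabulary, provenance = x@provenance)
})

#' @rdname perivasc-accessors
#' @export
setMethod("hullArea", "MembraneHull", function(x, ...) {
  abs(ringArea(x@exterior)) - sum(vapply(x@holes,
                                         function(h) abs(ringArea(h)),
                                         numeric(1)))
})

#' @rdname perivasc-accessors
#' @export
setMethod("marker", "MembraneHull", function(x, ...) x@marker)

#' @rdname perivasc-accessors
#' @export
setMethod("exprValues", "ExpressionMatrix", function(x, ...) x@values)

#' @rdname perivasc-accessors
#' @export
setMethod("geneIds", "ExpressionMatrix", function(x, ...) rownames(x@values))

#' @rdname perivasc-accessors
#' @export
setMethod("unitIds", "ExpressionMatrix", function(x, ...) colnames(x@values))

#' @rdname perivasc-accessors
#' @export
setMethod("fieldValues", "DensityField", function(x, ...) x@values)

#' @rdname perivasc-accessors
#' @export
setMethod("fieldMask", "DensityField", function(x, ...) x@mask)

#' @rdname perivasc-accessors
#' @export
setMethod("gridNodes", "DensityField", function(x, ...) {
  list(x = x@origin[1] + (seq_len(nrow(x@values)) - 1) * x@spacing,
       y = x@origin[2] + (seq_len(ncol(x@values)) - 1) * x@spacing)
})

setMethod("show", "CellMap", function(object) {
  cat(sprintf("CellMap with %d cells, %d sample(s)\n",
              nCells(object), length(unique(object@cells$sample_id))))
  tab <- table(factor(object@cells$phenotype, levels = object@vocabulary))
  tab <- tab[tab > 0]
  if (length(tab))
    cat("  phenotypes:",
        paste(sprintf("%s=%d", names(tab), tab), collapse = ", "), "\n")
})

setMethod("show", "MembraneHull", function(object) {
  cat(sprintf("MembraneHull [%s]: %d vertices, %d hole(s), area %.1f um^2\n",
              object@marker, nrow(object@exterior), length(object@holes),
              hullArea(object)))
})

setMethod("show", "ExpressionMatrix", function(object) {
  cat(sprintf("ExpressionMatrix (%s): %d genes x %d units\n",
              object@valueKind, nrow(object@values), ncol(object@values)))
})

setMethod("show", "DensityField", function(object) {
  cat(sprintf(
    "DensityField (%s): %d x %d grid, spacing %.3g um, sigma %.3g um\n",
    object@kind, nrow(object@values), ncol(object@values),
    object@spacing, object@sigma))
})

setMethod("show", "NNZResult", function(object) {
  cat(sprintf("NNZResult %s -> %s (n=%d/%d, %s, %d perms)\n",
              object@fromType, object@toType, object@nFrom, object@nTo,
              object@mode, object@nPerm))
  if (object@undefined) {
    cat("  undefined statistic (degenerate null or missing type)\n")
  } else {
    cat(sprintf("  observed %.3f um, null %.3f +/- %.3f um, z = %.3f\n",
                object@observedMeanNN, object@nullMean, object@nullSd,
                object@z))
  }
})

setMethod("show", "KSResult", function(object) {
  cat(sprintf(
    "KSResult: D = %.5f, p = %.4g (n = %d vs %d, medians %.1f / %.1f um)\n",
    object@D, object@pValue, object@nPos, object@nNeg,
    object@medianPos, object@medianNeg))
})
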