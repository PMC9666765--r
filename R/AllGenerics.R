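# Accessor generics -- slot access stays behind these.

#' Accessors for poriaNIR containers
#'
#' `wavenumbers()` returns the wavenumber axis (cm\eqn{^{-1}});
#' `absorbance()` the wavenumber x scan absorbance matrix; `classLabels()`,
#' `sampleIds()` and `replicateIds()` the per-scan metadata; `phiMatrix()`
#' the synchronous correlation matrix; `gridValues()` and `gridHeaderOf()`
#' a raster's cell matrix and ESRI header.
#'
#' @param x the object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("wavenumbers", function(x) standardGeneric("wavenumbers"))
#' @rdname accessors
#' @export
setGeneric("absorbance", function(x) standardGeneric("absorbance"))
#' @rdname accessors
#' @export
setGeneric("classLabels", function(x) standardGeneric("classLabels"))
#' @rdname accessors
#' @export
setGeneric("sampleIds", function(x) standardGeneric("sampleIds"))
#' @rdname accessors
#' @export
setGeneric("replicateIds", function(x) standardGeneric("replicateIds"))
#' @rdname accessors
#' @export
setGeneric("phiMatrix", function(x) standardGeneric("phiMatrix"))
#' @rdname accessors
#' @export
setGeneric("gridValues", function(x) standardGeneric("gridValues"))
#' @rdname accessors
#' @export
setGeneric("gridHeaderOf", function(x) standardGeneric("gridHeaderOf"))

#' @rdname accessors
setMethod("wavenumbers", "NIRSpectra", function(x)
  SummarizedExperiment::rowData(x)$wavenumber)
#' @rdname accessors
setMethod("absorbance", "NIRSpectra", function(x)
  SummarizedExperiment::assay(x, "absorbance"))
#' @rdname accessors
setMethod("classLabels", "NIRSpectra", function(x)
  SummarizedExperiment::colData(x)$class)
#' @rdname accessors
setMethod("sampleIds", "NIRSpectra", function(x)
  SummarizedExperiment::colData(x)$sample_id)
#' @rdname accessors
setMethod("replicateIds", "NIRSpectra", function(x)
  SummarizedExperiment::colData(x)$replicate)

#' @rdname accessors
setMethod("wavenumbers", "DynamicSpectra", function(x) x@wavenumber)
#' @rdname accessors
setMethod("wavenumbers", "SyncMap", function(x) x@wavenumber)
#' @rdname accessors
setMethod("phiMatrix", "SyncMap", function(x) x@phi)
#' @rdname accessors
setMethod("gridValues", "GridLayer", function(x) x@grid)
#' @rdname accessors
setMethod("gridHeaderOf", "GridLayer", function(x) x@header)

setMethod("show", "NIRSpectra", function(object) {
  cat("NIRSpectra:", ncol(object), "scans x", nrow(object), "wavenumbers\n")
  wn <- wavenumbers(object)
  cat("  axis:", min(wn), "-", max(wn), "cm^-1\n")
  cl <- table(classLabels(object))
  cat("  classes:", paste(names(cl), cl, sep = "=", collapse = ", "), "\n")
})

setMethod("show", "SyncMap", function(object) {
  p <- length(object@wavenumber)
  cat("SyncMap:", p, "x", p, "synchronous 2DCOS map,",
      "axis", min(object@wavenumber), "-", max(object@wavenumber), "cm^-1\n")
  cat("  intensity range:", format(range(object@phi), digits = 4), "\n")
})

setMethod("show", "DynamicSpectra", function(object) {
  cat("DynamicSpectra:", nrow(object@dyn), "perturbation points x",
      ncol(object@dyn), "wavenumbers\n")
})

setMethod("show", "GridLayer", function(object) {
  h <- object@header
  cat(class(object), ":", h$nrows, "x", h$ncols, "cells, cellsize",
      h$cellsize, "\n")
  cat("  nodata cells:", sum(is.na(object@grid)), "\n")
})
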