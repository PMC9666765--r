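#' @import SummarizedExperiment
#' @import S4Vectors
NULL

# ---------------------------------------------------------------------------
# NIRSpectra: a SummarizedExperiment whose rows are wavenumbers (cm^-1) and
# whose columns are individual scans. rowData carries the axis; colData the
# sample metadata (sample_id, class, part, status, replicate).
# ---------------------------------------------------------------------------

#' Container for FT-NIR spectral collections
#'
#' `NIRSpectra` extends [SummarizedExperiment::SummarizedExperiment] with rows
#' indexed by a strictly increasing wavenumber axis (cm\eqn{^{-1}}) and one
#' column per scan. The single assay, `"absorbance"`, holds dimensionless
#' absorbance values. Column metadata records `sample_id`, `class`, `part`
#' (`"poria"` or `"cutis"`), `status` (`"wild"` or `"cultivated"`) and
#' `replicate`.
#'
#' @slot All slots inherited from `SummarizedExperiment`.
#' @seealso [NIRSpectra()] for construction, [wavenumbers()], [absorbance()],
#'   [classLabels()] for access.
#' @export
setClass("NIRSpectra", contains = "SummarizedExperiment")

setValidity("NIRSpectra", function(object) {
  msg <- character()
  if (!"absorbance" %in% SummarizedExperiment::assayNames(object))
    msg <- c(msg, "assay 'absorbance' is required")
  wn <- SummarizedExperiment::rowData(object)$wavenumber
  if (is.null(wn)) {
    msg <- c(msg, "rowData column 'wavenumber' is required")
  } else {
    if (length(wn) < 2) msg <- c(msg, "wavenumber axis needs at least 2 points")
    if (any(diff(wn) <= 0)) msg <- c(msg, "wavenumber axis must be strictly increasing")
  }
  if (length(msg) == 0 && any(!is.finite(SummarizedExperiment::assay(object, "absorbance"))))
    msg <- c(msg, "absorbance values must all be finite")
  cd <- SummarizedExperiment::colData(object)
  need <- c("sample_id", "class", "replicate")
  miss <- setdiff(need, colnames(cd))
  if (length(miss)) msg <- c(msg, paste("colData misses:", paste(miss, collapse = ", ")))
  if (length(msg) == 0) {
    key <- paste(cd$sample_id, cd$replicate)
    if (anyDuplicated(key))
      msg <- c(msg, "sample_id must be unique within a replicate")
  }
  if (length(msg)) msg else TRUE
})

#' Construct an NIRSpectra collection
#'
#' @param absorbance numeric matrix, wavenumbers in rows and scans in columns.
#' @param wavenumber strictly increasing numeric axis in cm\eqn{^{-1}}, one
#'   value per row of `absorbance`.
#' @param sampleId character vector of sample identifiers, one per column.
#' @param classLabel character vector of class labels (recycled if length 1).
#' @param replicate integer replicate index per column (default 1).
#' @param part,status optional per-column annotations; when missing they are
#'   parsed from `classLabel` values of the form `"wild-poria"` etc. and left
#'   `NA` otherwise.
#' @return A validated [NIRSpectra-class] object.
#' @examples
#' wn <- seq(4000, 10000, by = 100)
#' a <- matrix(runif(length(wn) * 2), ncol = 2)
#' sp <- NIRSpectra(a, wn, sampleId = c("s1", "s2"), classLabel = "wild-poria")
#' wavenumbers(sp)[1:3]
#' @export
NIRSpectra <- function(absorbance, wavenumber, sampleId,
                       classLabel = NA_character_, replicate = 1L,
                       part = NULL, status = NULL) {
  absorbance <- as.matrix(absorbance)
  n <- ncol(absorbance)
  classLabel <- rep_len(as.character(classLabel), n)
  replicate <- rep_len(as.integer(replicate), n)
  if (is.null(part))
    part <- ifelse(grepl("cutis", classLabel), "cutis",
                   ifelse(grepl("poria", classLabel), "poria", NA_character_))
  if (is.null(status))
    status <- ifelse(grepl("^wild", classLabel), "wild",
                     ifelse(grepl("^cultivated", classLabel), "cultivated",
                            NA_character_))
  cd <- S4Vectors::DataFrame(
    sample_id = as.character(sampleId),
    class = classLabel,
    part = rep_len(part, n),
    status = rep_len(status, n),
    replicate = replicate
  )
  colnames(absorbance) <- make.unique(paste0(cd$sample_id, "_r", cd$replicate))
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(absorbance = absorbance),
    rowData = S4Vectors::DataFrame(wavenumber = as.numeric(wavenumber)),
    colData = cd
  )
  methods::new("NIRSpectra", se)
}

# ---------------------------------------------------------------------------
# 2DCOS containers
# ---------------------------------------------------------------------------

#' Mean-centered perturbation-series matrix for 2DCOS
#'
#' Rows are perturbation points (here: samples), columns are wavenumbers;
#' entry (i, v) is the dynamic intensity, i.e. the spectrum at perturbation i
#' minus the reference spectrum.
#'
#' @slot dyn numeric m x p matrix of dynamic intensities.
#' @slot wavenumber numeric axis of length p.
#' @slot reference numeric reference spectrum of length p.
#' @seealso [dynamicSpectra()], [syncMap()]
#' @export
setClass("DynamicSpectra",
         representation(dyn = "matrix", wavenumber = "numeric",
                        reference = "numeric"))

setValidity("DynamicSpectra", function(object) {
  msg <- character()
  if (ncol(object@dyn) != length(object@wavenumber))
    msg <- c(msg, "ncol(dyn) must equal length(wavenumber)")
  if (length(object@reference) != length(object@wavenumber))
    msg <- c(msg, "reference length must equal axis length")
  if (nrow(object@dyn) < 1) msg <- c(msg, "need at least one perturbation point")
  if (length(msg)) msg else TRUE
})

#' Synchronous two-dimensional correlation map
#'
#' The symmetric p x p matrix of synchronous correlation intensities over all
#' wavenumber pairs. Auto peaks (the diagonal) are non-negative.
#'
#' @slot phi numeric symmetric p x p matrix.
#' @slot wavenumber numeric axis of length p, shared by both dimensions.
#' @seealso [syncMap()], [perSampleSyncMap()], [renderMap()]
#' @export
setClass("SyncMap",
         representation(phi = "matrix", wavenumber = "numeric"))

setValidity("SyncMap", function(object) {
  msg <- character()
  p <- length(object@wavenumber)
  if (!all(dim(object@phi) == c(p, p)))
    msg <- c(msg, "phi must be p x p with p = length(wavenumber)")
  else {
    tol <- 1e-8 * max(1, max(abs(object@phi)))
    if (max(abs(object@phi - t(object@phi))) > tol)
      msg <- c(msg, "phi must be symmetric")
    if (min(diag(object@phi)) < -tol)
      msg <- c(msg, "auto peaks (diagonal) must be non-negative")
  }
  if (length(msg)) msg else TRUE
})

# ---------------------------------------------------------------------------
# Raster containers (ESRI ASCII grid semantics: row 1 = northernmost row)
# ---------------------------------------------------------------------------

#' Gridded geospatial layer (ESRI ASCII grid semantics)
#'
#' A numeric matrix plus the six-field ESRI ASCII header. Row 1 is the
#' northernmost row; nodata cells are stored as `NA`.
#'
#' @slot grid numeric matrix (`NA` = nodata).
#' @slot header named list with `ncols`, `nrows`, `xllcorner`, `yllcorner`,
#'   `cellsize`, `nodata_value`.
#' @seealso [readAsciiGrid()], [writeAsciiGrid()]
#' @export
setClass("GridLayer", representation(grid = "matrix", header = "list"))

setValidity("GridLayer", function(object) {
  h <- object@header
  need <- c("ncols", "nrows", "xllcorner", "yllcorner", "cellsize", "nodata_value")
  miss <- setdiff(need, names(h))
  if (length(miss)) return(paste("header misses:", paste(miss, collapse = ", ")))
  if (nrow(object@grid) != h$nrows || ncol(object@grid) != h$ncols)
    return("grid dimensions disagree with header nrows/ncols")
  if (h$cellsize <= 0) return("cellsize must be positive")
  TRUE
})

#' Habitat-suitability raster
#'
#' A [GridLayer-class] whose valid cells are suitability indices in [0, 1],
#' as produced by a species-distribution model such as MaxEnt.
#'
#' @seealso [classifySuitability()]
#' @export
setClass("SuitabilityRaster", contains = "GridLayer")

setValidity("SuitabilityRaster", function(object) {
  v <- object@grid[!is.na(object@grid)]
  if (length(v) && (min(v) < 0 || max(v) > 1))
    return("suitability indices must lie in [0, 1]")
  TRUE
})

#' Binary suitable/unsuitable habitat map
#'
#' A [GridLayer-class] whose valid cells are 1 (suitable) or 0 (unsuitable);
#' nodata cells are `NA`.
#'
#' @seealso [classifySuitability()], [overlayHabitat()], [areaStats()]
#' @export
setClass("BinaryHabitatMap", contains = "GridLayer")

setValidity("BinaryHabitatMap", function(object) {
  v <- object@grid[!is.na(object@grid)]
  if (length(v) && !all(v %in% c(0, 1)))
    return("binary map cells must be 0, 1 or NA")
  TRUE
})

gridHeader <- function(nrows, ncols, xllcorner = 0, yllcorner = 0,
                       cellsize = 1, nodata_value = -9999) {
  list(ncols = as.integer(ncols), nrows = as.integer(nrows),
       xllcorner = xllcorner, yllcorner = yllcorner,
       cellsize = cellsize, nodata_value = nodata_value)
}

#' Construct a GridLayer / SuitabilityRaster / BinaryHabitatMap
#'
#' @param grid numeric matrix; `NA` marks nodata cells.
#' @param header optional header list as in [GridLayer-class]; a default
#'   unit-cell header is built when omitted.
#' @return the corresponding S4 object.
#' @export
GridLayer <- function(grid, header = NULL) {
  stopIf(!is.matrix(grid), "grid must be a matrix")
  if (is.null(header)) header <- gridHeader(nrow(grid), ncol(grid))
  methods::new("GridLayer", grid = grid, header = header)
}

#' @rdname GridLayer
#' @export
SuitabilityRaster <- function(grid, header = NULL) {
  stopIf(!is.matrix(grid), "grid must be a matrix")
  if (is.null(header)) header <- gridHeader(nrow(grid), ncol(grid))
  methods::new("SuitabilityRaster", grid = grid, header = header)
}

#' @rdname GridLayer
#' @export
BinaryHabitatMap <- function(grid, header = NULL) {
  stopIf(!is.matrix(grid), "grid must be a matrix")
  if (is.null(header)) header <- gridHeader(nrow(grid), ncol(grid))
  methods::new("BinaryHabitatMap", grid = grid, header = header)
}
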