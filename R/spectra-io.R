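# Reading, writing and preprocessing of spectral collections. Plain-CSV
# exchange format: first column `wavenumber_cm-1`, one column per scan, plus
# an optional metadata sidecar (column, sample_id, class, replicate).

#' Write a spectral collection to CSV
#'
#' @param x an [NIRSpectra-class] collection.
#' @param path output CSV; first column is `wavenumber_cm-1`, remaining
#'   columns are scans.
#' @param metadataPath optional sidecar CSV receiving per-scan metadata
#'   (`column`, `sample_id`, `class`, `part`, `status`, `replicate`).
#' @return invisibly, the file path(s) written.
#' @export
writeSpectraCSV <- function(x, path, metadataPath = NULL) {
  A <- absorbance(x)
  df <- data.frame(check.names = FALSE, `wavenumber_cm-1` = wavenumbers(x), A)
  utils::write.csv(df, path, row.names = FALSE)
  written <- path
  if (!is.null(metadataPath)) {
    cd <- as.data.frame(SummarizedExperiment::colData(x))
    md <- cbind(column = colnames(A), cd)
    utils::write.csv(md, metadataPath, row.names = FALSE)
    written <- c(path, metadataPath)
  }
  invisible(written)
}

#' Read a spectral collection from CSV
#'
#' The first column must hold the wavenumber axis; files stored with a
#' descending axis are reordered to the package's ascending convention (all
#' rows permuted consistently). Non-numeric or missing cells, ragged rows and
#' duplicate wavenumbers are rejected with a message naming the offender.
#'
#' @param path CSV as written by [writeSpectraCSV()].
#' @param metadataPath optional sidecar CSV; when present, `sample_id`,
#'   `class` and `replicate` are joined by column name.
#' @return an [NIRSpectra-class] collection.
#' @export
readSpectraCSV <- function(path, metadataPath = NULL) {
  stopIf(!file.exists(path), "file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = NA)
  stopIf(ncol(df) < 2, "file has no spectrum columns: ", path)
  for (j in seq_len(ncol(df))) {
    v <- df[[j]]
    if (!is.numeric(v)) {
      bad <- which(is.na(suppressWarnings(as.numeric(as.character(v)))))[1]
      stop("non-numeric cell in column '", colnames(df)[j], "', row ",
           if (is.na(bad)) "?" else bad, call. = FALSE)
    }
    if (anyNA(v)) {
      stop("missing/NaN cell in column '", colnames(df)[j], "', row ",
           which(is.na(v))[1], call. = FALSE)
    }
  }
  wn <- df[[1]]
  stopIf(anyDuplicated(wn) > 0, "duplicate wavenumber at row ",
         which(duplicated(wn))[1])
  ord <- order(wn)
  wn <- wn[ord]
  A <- as.matrix(df[ord, -1, drop = FALSE])
  cols <- colnames(A)
  sampleId <- cols; classLabel <- NA_character_; replicate <- 1L
  part <- NULL; status <- NULL
  if (!is.null(metadataPath)) {
    stopIf(!file.exists(metadataPath), "metadata file not found: ", metadataPath)
    md <- utils::read.csv(metadataPath, check.names = FALSE,
                          stringsAsFactors = FALSE)
    stopIf(!"column" %in% colnames(md), "metadata needs a 'column' field")
    i <- match(cols, md$column)
    stopIf(anyNA(i), "metadata misses column(s): ",
           paste(cols[is.na(i)], collapse = ", "))
    sampleId <- md$sample_id[i]
    if (!is.null(md$class)) classLabel <- md$class[i]
    if (!is.null(md$replicate)) replicate <- as.integer(md$replicate[i])
    if (!is.null(md$part)) part <- md$part[i]
    if (!is.null(md$status)) status <- md$status[i]
  }
  NIRSpectra(A, wn, sampleId = sampleId, classLabel = classLabel,
             replicate = replicate, part = part, status = status)
}

#' Average replicate scans per sample
#'
#' Each sample's scans (rows of colData sharing `sample_id`) are averaged
#' pointwise into one spectrum, the standard treatment when each specimen is
#' scanned twice in parallel. Replicates of one sample must agree on their
#' class label.
#'
#' @param x an [NIRSpectra-class] collection.
#' @return an [NIRSpectra-class] with one column per `sample_id`
#'   (`replicate = 1`), in order of first appearance.
#' @export
averageReplicates <- function(x) {
  cd <- SummarizedExperiment::colData(x)
  ids <- unique(cd$sample_id)
  A <- absorbance(x)
  out <- matrix(NA_real_, nrow = nrow(A), ncol = length(ids))
  cls <- part <- status <- character(length(ids))
  for (k in seq_along(ids)) {
    j <- which(cd$sample_id == ids[k])
    ucls <- unique(cd$class[j])
    stopIf(length(ucls) > 1, "replicates of sample '", ids[k],
           "' carry conflicting class labels: ", paste(ucls, collapse = " vs "))
    out[, k] <- rowMeans(A[, j, drop = FALSE])
    cls[k] <- ucls
    part[k] <- cd$part[j[1]]; status[k] <- cd$status[j[1]]
  }
  NIRSpectra(out, wavenumbers(x), sampleId = ids, classLabel = cls,
             replicate = 1L, part = part, status = status)
}

#' Pointwise mean spectrum of a collection
#'
#' @param x a non-empty [NIRSpectra-class] collection.
#' @return an [NIRSpectra-class] with a single column, `class` set to the
#'   collection's label when uniform and `"mixed"` otherwise.
#' @export
meanSpectrum <- function(x) {
  stopIf(ncol(x) == 0, "cannot take the mean of an empty collection")
  cls <- unique(classLabels(x))
  lab <- if (length(cls) == 1) cls else "mixed"
  NIRSpectra(matrix(rowMeans(absorbance(x)), ncol = 1), wavenumbers(x),
             sampleId = "mean", classLabel = lab)
}
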