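# Generalized synchronous two-dimensional correlation spectroscopy.
# The dynamic spectrum is the perturbation series minus a reference; the
# synchronous map is Phi = S^T S / (m - 1), symmetric and PSD, with auto
# peaks on the diagonal and cross peaks off it.

#' Dynamic (reference-subtracted) spectra
#'
#' Builds the m x p dynamic-intensity matrix whose row i is spectrum i minus
#' the reference. With the default mean reference the columns have zero mean.
#'
#' @param x an [NIRSpectra-class] collection (m scans, shared axis).
#' @param reference `"mean"` (default: the collection mean) or a numeric
#'   spectrum on the same axis.
#' @return a [DynamicSpectra-class] object.
#' @export
dynamicSpectra <- function(x, reference = "mean") {
  stopIf(ncol(x) == 0, "empty collection")
  A <- t(absorbance(x))  # m x p
  if (identical(reference, "mean")) {
    ref <- colMeans(A)
  } else {
    ref <- as.numeric(reference)
    stopIf(length(ref) != ncol(A),
           "reference length ", length(ref), " does not match axis length ",
           ncol(A))
  }
  methods::new("DynamicSpectra", dyn = sweep(A, 2, ref),
               wavenumber = wavenumbers(x), reference = ref)
}

#' Synchronous 2DCOS map of a perturbation series
#'
#' Phi(v1, v2) = S(v1)^T S(v2) / (m - 1) over the m perturbation points.
#' The result is symmetric positive semidefinite; the diagonal holds the
#' auto peaks.
#'
#' @param dyn a [DynamicSpectra-class] with m >= 2 rows.
#' @return a [SyncMap-class].
#' @export
syncMap <- function(dyn) {
  m <- nrow(dyn@dyn)
  stopIf(m < 2,
         "the synchronous map needs m >= 2 perturbation points (the 1/(m-1) ",
         "normalization); for a single spectrum use perSampleSyncMap()")
  phi <- crossprod(dyn@dyn) / (m - 1)
  phi <- (phi + t(phi)) / 2  # kill round-off asymmetry
  methods::new("SyncMap", phi = phi, wavenumber = dyn@wavenumber)
}

#' Per-sample synchronous map (rank-1 self-correlation)
#'
#' For a single observation the perturbation series degenerates; the
#' per-sample map is the outer product of the sample's deviation from a
#' reference spectrum, d = s - ref, giving Phi = d d^T. This preserves the
#' synchronous map's structure (symmetry, positive semidefiniteness,
#' non-negative diagonal auto peaks) for one spectrum and is the image fed
#' to the classifier, one map per sample.
#'
#' @param x a numeric spectrum, or an [NIRSpectra-class] collection.
#' @param reference numeric reference spectrum on the same axis (for the
#'   `NIRSpectra` method, `"mean"` uses the collection mean).
#' @param wavenumber axis for the numeric method.
#' @param sample for the `NIRSpectra` method: column index or sample id.
#' @return a [SyncMap-class].
#' @export
setGeneric("perSampleSyncMap",
           function(x, reference, ...) standardGeneric("perSampleSyncMap"))

#' @rdname perSampleSyncMap
#' @export
setMethod("perSampleSyncMap", "numeric",
          function(x, reference, wavenumber = seq_along(x)) {
  stopIf(length(reference) != length(x),
         "spectrum and reference lengths differ (",
         length(x), " vs ", length(reference), ")")
  d <- x - as.numeric(reference)
  methods::new("SyncMap", phi = tcrossprod(d), wavenumber = wavenumber)
})

#' @rdname perSampleSyncMap
#' @export
setMethod("perSampleSyncMap", "NIRSpectra",
          function(x, reference = "mean", sample = 1L) {
  if (is.character(sample)) {
    sample <- match(sample, sampleIds(x))
    stopIf(is.na(sample), "sample id not found")
  }
  ref <- if (identical(reference, "mean")) rowMeans(absorbance(x))
         else as.numeric(reference)
  perSampleSyncMap(absorbance(x)[, sample], ref, wavenumber = wavenumbers(x))
})

# ---------------------------------------------------------------------------
# Rendering
# ---------------------------------------------------------------------------

builtinColormaps <- list(
  jet = c("#00007F", "#0000FF", "#00FFFF", "#00FF00",
          "#FFFF00", "#FF7F00", "#FF0000"),
  viridis = c("#440154", "#414487", "#2A788E", "#22A884",
              "#7AD151", "#FDE725"),
  grey = c("#000000", "#FFFFFF")
)

#' Render a synchronous map as a filled-contour image
#'
#' The map is resampled to `sizePx` x `sizePx` (nearest cell), quantized
#' into `nLevels` filled-contour bands symmetric about zero (so sign
#' structure is preserved), and colored through a built-in colormap. The
#' pixel grid has no axes or margins; wavenumber ascends with row and column
#' index, and files are written with wavenumber ascending left-to-right and
#' bottom-to-top. Rendering and PNG output are deterministic: two renders of
#' one map are byte-identical.
#'
#' @param map a [SyncMap-class].
#' @param sizePx output side length in pixels (>= 16), default 224.
#' @param nLevels number of contour bands, default 16.
#' @param colormap `"jet"` (rainbow-style, default), `"viridis"` or `"grey"`.
#' @param file optional path; format from extension or `format`.
#' @param format `"png"` (default, lossless) or `"jpeg"` (requires EBImage).
#' @return invisibly, a list of class `"MapImage"`: `pixels` (sizePx x
#'   sizePx x 3 RGB in [0,1], row/col index ascending in wavenumber),
#'   `levels` (the quantized band index matrix), `sizePx`, `nLevels`,
#'   `colormap`, `file`.
#' @export
renderMap <- function(map, sizePx = 224, nLevels = 16, colormap = "jet",
                      file = NULL, format = c("png", "jpeg")) {
  stopIf(sizePx < 16, "sizePx must be >= 16")
  format <- match.arg(format)
  phi <- phiMatrix(map)
  p <- nrow(phi)
  idx <- floor((seq_len(sizePx) - 0.5) * p / sizePx) + 1
  sub <- phi[idx, idx, drop = FALSE]
  vmax <- max(abs(sub))
  lev <- if (vmax == 0) matrix(ceiling(nLevels / 2), sizePx, sizePx)
         else pmin(pmax(ceiling((sub + vmax) / (2 * vmax) * nLevels), 1),
                   nLevels)
  pal <- grDevices::colorRamp(builtinColormaps[[colormap]])(
    (seq_len(nLevels) - 0.5) / nLevels) / 255
  pix <- array(0, c(sizePx, sizePx, 3))
  for (ch in 1:3) pix[, , ch] <- matrix(pal[lev, ch], sizePx, sizePx)
  img <- structure(list(pixels = pix, levels = lev, sizePx = sizePx,
                        nLevels = nLevels, colormap = colormap, file = file),
                   class = "MapImage")
  if (!is.null(file)) writeMapImage(img, file, format)
  invisible(img)
}

# Write a MapImage to disk; rows are flipped so wavenumber ascends
# bottom-to-top in the displayed file.
writeMapImage <- function(img, file, format = c("png", "jpeg")) {
  format <- match.arg(format)
  if (grepl("\\.jpe?g$", file, ignore.case = TRUE)) format <- "jpeg"
  disp <- img$pixels[rev(seq_len(img$sizePx)), , , drop = FALSE]
  if (format == "png") {
    png::writePNG(disp, target = file)
  } else {
    if (!requireNamespace("EBImage", quietly = TRUE))
      stop("JPEG output requires the EBImage package", call. = FALSE)
    # EBImage expects x = width, y = height
    EBImage::writeImage(EBImage::Image(aperm(disp, c(2, 1, 3)),
                                       colormode = "Color"),
                        file, type = "jpeg", quality = 100)
  }
  invisible(file)
}

# Classifier-ready tensor (channels, height, width) from a MapImage.
mapImageTensor <- function(img) aperm(img$pixels, c(3, 1, 2))

#' Average several spectra onto a coarser axis by binning
#'
#' Splits the axis into `nBins` contiguous equal-count bins and replaces each
#' bin by its mean wavenumber and mean absorbance. Used to bring full-
#' resolution spectra down to the working resolution of per-sample 2DCOS
#' maps.
#'
#' @param x an [NIRSpectra-class].
#' @param nBins number of output points (>= 2, <= axis length).
#' @return a binned [NIRSpectra-class].
#' @export
binSpectra <- function(x, nBins = 64) {
  p <- nrow(x)
  stopIf(nBins < 2 || nBins > p, "nBins must be in [2, axis length]")
  grp <- ceiling(seq_len(p) / (p / nBins))
  grp <- pmin(grp, nBins)
  wn <- as.vector(tapply(wavenumbers(x), grp, mean))
  A <- rowsum(absorbance(x), grp) / as.vector(table(grp))
  cd <- SummarizedExperiment::colData(x)
  NIRSpectra(A, wn, sampleId = cd$sample_id, classLabel = cd$class,
             replicate = cd$replicate, part = cd$part, status = cd$status)
}
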