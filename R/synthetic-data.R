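# Synthetic FT-NIR generator. Emulates the statistical structure of W. cocos
# spectra: six absorption bands, a linear baseline, iid Gaussian noise, and
# class effects in which the part (Poria vs Poriae Cutis) moves band
# amplitudes much more than the cultivation status (wild vs cultivated).

#' Default wavenumber axis
#'
#' Ascending axis over 4000-10000 cm\eqn{^{-1}}. The default spacing of
#' 3.857 cm\eqn{^{-1}} is the digitization interval typical of an FT-NIR
#' instrument operated at 8 cm\eqn{^{-1}} resolution.
#'
#' @param from,to axis limits in cm\eqn{^{-1}}.
#' @param by spacing in cm\eqn{^{-1}}.
#' @return strictly increasing numeric vector.
#' @export
defaultWavenumberAxis <- function(from = 4000, to = 10000, by = 3.857) {
  seq(from, to, by = by)
}

#' Specify one absorption band
#'
#' @param center band center in cm\eqn{^{-1}} (4000-10000).
#' @param width Gaussian sigma in cm\eqn{^{-1}} (> 0).
#' @param amplitude peak absorbance (>= 0, dimensionless).
#' @return a one-row data.frame with columns `center`, `width`, `amplitude`.
#' @export
bandSpec <- function(center, width, amplitude) {
  stopIf(center < 4000 || center > 10000,
         "band center must lie in 4000-10000 cm^-1, got ", center)
  stopIf(width <= 0, "band width must be > 0")
  stopIf(amplitude < 0, "band amplitude must be >= 0")
  data.frame(center = center, width = width, amplitude = amplitude)
}

#' Default W. cocos band table
#'
#' Six Gaussian bands at the midpoints of the characteristic FT-NIR
#' absorption regions of W. cocos: the C=C-H second overtone of unsaturated
#' lipids (8380-8230 cm\eqn{^{-1}}), the O-H first overtone (~6870), the C-H
#' first overtone (5730-5560), the polysaccharide O-H combination band
#' (~5180), the amide combination band of proteins (4985-4515) and the C-H
#' stretch/deformation combination (4320-4255). Widths and amplitudes are
#' documented package defaults; absorbance magnitudes are not reported for
#' real material, so these are chosen to resemble a typical diffuse-
#' reflectance FT-NIR spectrum.
#'
#' @return data.frame with columns `center`, `width`, `amplitude` (6 rows).
#' @examples
#' defaultBandTable()
#' @export
defaultBandTable <- function() {
  rbind(
    bandSpec(8305,   80, 0.10),
    bandSpec(6870,   60, 0.28),
    bandSpec(5645,   45, 0.22),
    bandSpec(5180,   35, 0.42),
    bandSpec(4750,  110, 0.30),
    bandSpec(4287.5, 25, 0.15)
  )
}

#' Define a class profile for the generator
#'
#' @param label class name (e.g. `"wild-poria"`), unique per generator run.
#' @param bands band table as from [defaultBandTable()]; per-class amplitude
#'   effects are already folded into `amplitude`.
#' @param baselineOffset,baselineSlope linear baseline: absorbance offset and
#'   slope per cm\eqn{^{-1}} relative to the axis start.
#' @param noiseSd standard deviation of the iid Gaussian measurement noise
#'   (absorbance units, >= 0).
#' @return list with class `"ClassProfile"`.
#' @export
classProfile <- function(label, bands = defaultBandTable(),
                         baselineOffset = 0.1, baselineSlope = 0,
                         noiseSd = 0.002) {
  stopIf(noiseSd < 0, "noiseSd must be >= 0")
  stopIf(nrow(bands) < 1, "a class profile needs at least one band")
  structure(list(label = label, bands = bands,
                 baselineOffset = baselineOffset,
                 baselineSlope = baselineSlope, noiseSd = noiseSd),
            class = "ClassProfile")
}

#' Default four-class profiles
#'
#' Builds the four study classes (wild/cultivated x Poria/Poriae Cutis) from
#' the default band table. Band amplitudes are modulated multiplicatively:
#' the part effect moves amplitudes by `partEffect/2` up or down (sign
#' alternating across bands) and the status effect by `statusEffect/2`. The
#' default 0.25 vs 0.05 encodes a part effect five times the status effect,
#' mirroring PCA score structure in which the two parts separate strongly
#' while wild and cultivated overlap. With the default amplitudes the
#' smallest wild-vs-cultivated band-amplitude difference is about
#' `statusEffect * 0.10` absorbance, i.e. 5 x `noiseSd` at the defaults.
#'
#' @param partEffect,statusEffect relative amplitude modulation (fractions).
#' @param noiseSd measurement-noise SD in absorbance units.
#' @param bands base band table.
#' @return named list of four `ClassProfile`s: `wild-poria`,
#'   `cultivated-poria`, `wild-cutis`, `cultivated-cutis`.
#' @export
defaultClassProfiles <- function(partEffect = 0.25, statusEffect = 0.05,
                                 noiseSd = 0.002, bands = defaultBandTable()) {
  dPart <- c(1, -1, 1, -1, 1, -1)[seq_len(nrow(bands))]
  dStat <- c(-1, 1, 1, -1, -1, 1)[seq_len(nrow(bands))]
  dPart[is.na(dPart)] <- 1; dStat[is.na(dStat)] <- 1
  mk <- function(label, sPart, sStat, off, slope) {
    b <- bands
    b$amplitude <- b$amplitude *
      (1 + sPart * partEffect / 2 * dPart) *
      (1 + sStat * statusEffect / 2 * dStat)
    classProfile(label, b, baselineOffset = off, baselineSlope = slope,
                 noiseSd = noiseSd)
  }
  list(
    "wild-poria"       = mk("wild-poria",        +1, +1, 0.10, 4e-6),
    "cultivated-poria" = mk("cultivated-poria",  +1, -1, 0.10, 4e-6),
    "wild-cutis"       = mk("wild-cutis",        -1, +1, 0.12, 6e-6),
    "cultivated-cutis" = mk("cultivated-cutis",  -1, -1, 0.12, 6e-6)
  )
}

# Noiseless template spectrum of a profile on an axis.
profileTemplate <- function(profile, axis) {
  out <- profile$baselineOffset + profile$baselineSlope * (axis - axis[1])
  b <- profile$bands
  outside <- b$center < min(axis) | b$center > max(axis)
  if (any(outside))
    warning("band center(s) ", paste(b$center[outside], collapse = ", "),
            " outside the axis range; band truncated", call. = FALSE)
  for (j in seq_len(nrow(b)))
    out <- out + b$amplitude[j] * exp(-(axis - b$center[j])^2 / (2 * b$width[j]^2))
  out
}

#' Generate one synthetic spectrum
#'
#' Absorbance = sum of Gaussian bands + linear baseline + iid Gaussian noise.
#' Deterministic for a fixed seed.
#'
#' @param profile a `ClassProfile`.
#' @param axis wavenumber axis (ascending).
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return numeric absorbance vector along `axis`.
#' @export
generateSpectrum <- function(profile, axis = defaultWavenumberAxis(),
                             seed = NULL) {
  template <- profileTemplate(profile, axis)
  withSeed(seed, template + rnorm(length(axis), sd = profile$noiseSd))
}

#' Generate a labelled synthetic dataset
#'
#' Default class counts (347, 165, 175, 152) reproduce the study's sample
#' sizes: 512 Poria (347 wild + 165 cultivated) and 327 Poriae Cutis (175
#' wild + 152 cultivated), 839 in total. With `replicates = 2` each sample
#' is scanned twice (noise redrawn) to exercise replicate averaging.
#'
#' @param profiles named list of `ClassProfile`s.
#' @param nPerClass integer vector of class sizes, same length as `profiles`.
#' @param axis wavenumber axis.
#' @param seed integer seed driving all noise draws.
#' @param replicates scans per sample (>= 1).
#' @return an [NIRSpectra-class] collection.
#' @examples
#' pr <- defaultClassProfiles()
#' sp <- generateDataset(pr, nPerClass = c(3, 3, 3, 3), seed = 1)
#' table(classLabels(sp))
#' @export
generateDataset <- function(profiles = defaultClassProfiles(),
                            nPerClass = c(347L, 165L, 175L, 152L),
                            axis = defaultWavenumberAxis(), seed = 1,
                            replicates = 1L) {
  stopIf(length(profiles) != length(nPerClass),
         "profiles and nPerClass lengths differ")
  stopIf(any(nPerClass <= 0), "all class counts must be positive")
  labels <- vapply(profiles, `[[`, "", "label")
  stopIf(anyDuplicated(labels) > 0, "class labels must be unique")
  templates <- lapply(profiles, profileTemplate, axis = axis)
  p <- length(axis)
  total <- sum(nPerClass) * replicates
  withSeed(seed, {
    noise <- matrix(rnorm(p * total), nrow = p)
  })
  A <- matrix(NA_real_, nrow = p, ncol = total)
  ids <- cls <- character(total); rep_ <- integer(total)
  k <- 0
  for (i in seq_along(profiles)) {
    for (s in seq_len(nPerClass[i])) {
      for (r in seq_len(replicates)) {
        k <- k + 1
        A[, k] <- templates[[i]] + profiles[[i]]$noiseSd * noise[, k]
        ids[k] <- sprintf("%s_%03d", labels[i], s)
        cls[k] <- labels[i]
        rep_[k] <- r
      }
    }
  }
  NIRSpectra(A, axis, sampleId = ids, classLabel = cls, replicate = rep_)
}

#' Generate raster fixtures for the habitat stage
#'
#' Builds spatially smooth random suitability fields in [0, 1] for climate
#' and soil (bilinear upsampling of a coarse uniform field), a vegetation
#' class grid drawn from the documented code list (1 = coniferous forest,
#' 2 = mixed coniferous forest, 3 = broad-leaved forest, 4 = grassland,
#' 5 = shrubland, 6 = cropland, 7 = urban, 8 = water) with spatial
#' structure, and contiguous region labels (`"R1"`, `"R2"`, ...) as the
#' Voronoi cells of random seed points. Stands in for species-distribution-
#' model outputs so the overlay/area pipeline is testable offline.
#'
#' @param rows,cols grid dimensions (>= 1).
#' @param nRegions number of contiguous regions.
#' @param seed integer seed.
#' @param cellAreaKm2 area of one cell in km\eqn{^2}.
#' @param nodataFrac fraction of cells masked as nodata (same mask in all
#'   layers, placed along the grid edge).
#' @return list of class `"RasterFixture"`: `climate` and `soil`
#'   ([SuitabilityRaster-class]), `vegetation` (integer matrix), `regions`
#'   (character matrix), `cellAreaKm2`, `vegetationCodes`.
#' @export
generateRasterFixture <- function(rows, cols, nRegions = 3, seed = 1,
                                  cellAreaKm2 = 1, nodataFrac = 0.05) {
  stopIf(rows < 1 || cols < 1, "rows and cols must be >= 1")
  withSeed(seed, {
    smoothField <- function() {
      cr <- max(2, ceiling(rows / 5)); cc <- max(2, ceiling(cols / 5))
      coarse <- matrix(runif(cr * cc), cr, cc)
      ri <- seq(1, cr, length.out = rows); ci <- seq(1, cc, length.out = cols)
      r0 <- pmin(floor(ri), cr - 1); c0 <- pmin(floor(ci), cc - 1)
      fr <- ri - r0; fc <- ci - c0
      f <- outer(seq_len(rows), seq_len(cols), function(i, j) {
        (1 - fr[i]) * (1 - fc[j]) * coarse[cbind(r0[i], c0[j])] +
          fr[i] * (1 - fc[j]) * coarse[cbind(r0[i] + 1, c0[j])] +
          (1 - fr[i]) * fc[j] * coarse[cbind(r0[i], c0[j] + 1)] +
          fr[i] * fc[j] * coarse[cbind(r0[i] + 1, c0[j] + 1)]
      })
      rng <- range(f)
      if (diff(rng) < .Machine$double.eps) matrix(0.5, rows, cols)
      else (f - rng[1]) / diff(rng)
    }
    climate <- smoothField()
    soil <- smoothField()
    vegField <- smoothField()
    vegCodes <- 1:8
    veg <- matrix(vegCodes[pmin(8, 1 + floor(vegField * 8))], rows, cols)
    nSeed <- max(1, nRegions)
    sr <- runif(nSeed, 1, rows); sc <- runif(nSeed, 1, cols)
    regIdx <- outer(seq_len(rows), seq_len(cols), function(i, j) {
      d <- outer(rep(1, length(i)), seq_len(nSeed))
      for (k in seq_len(nSeed)) d[, k] <- (i - sr[k])^2 + (j - sc[k])^2
      max.col(-d, ties.method = "first")
    })
    regions <- matrix(paste0("R", regIdx), rows, cols)
    nMask <- floor(nodataFrac * rows * cols)
    if (nMask > 0) {
      idx <- seq_len(nMask)  # deterministic strip along the first row(s)
      climate[idx] <- NA; soil[idx] <- NA
      veg[idx] <- NA; regions[idx] <- NA
    }
  })
  structure(list(
    climate = SuitabilityRaster(climate),
    soil = SuitabilityRaster(soil),
    vegetation = veg,
    regions = regions,
    cellAreaKm2 = cellAreaKm2,
    vegetationCodes = c(coniferous = 1, mixed_coniferous = 2,
                        broadleaved = 3, grassland = 4, shrubland = 5,
                        cropland = 6, urban = 7, water = 8)
  ), class = "RasterFixture")
}
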