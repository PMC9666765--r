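# End-to-end orchestration: simulate -> (average replicates) -> bin ->
# split -> per-sample 2DCOS images -> per-part ResNet -> evaluation, with a
# reproducibility manifest. One config object drives every stage; all
# randomness derives from the single seed.

#' Pipeline configuration
#'
#' Validates and assembles the parameters of every stage. Class sizes,
#' spectral axis, split fractions, 2DCOS imaging options, network
#' hyperparameters and the output directory live here; all stages derive
#' their randomness from `seed`.
#'
#' @param nPerClass samples per class (wild-poria, cultivated-poria,
#'   wild-cutis, cultivated-cutis).
#' @param partEffect,statusEffect,noiseSd generator separation parameters,
#'   see [defaultClassProfiles()].
#' @param replicates scans per sample; replicate averaging runs when > 1.
#' @param axis wavenumber axis.
#' @param nBins working spectral resolution for per-sample 2DCOS maps.
#' @param fractions train/test/external fractions, must sum to 1.
#' @param imageSize rendered image side in pixels.
#' @param nLevels,colormap contour rendering options, see [renderMap()].
#' @param parts which per-part wild-vs-cultivated models to train
#'   (`"poria"`, `"cutis"`).
#' @param epochs,batchSize,lr,weightDecay,momentum,channels network
#'   hyperparameters, see [resnetConfig()].
#' @param outputDir directory for artifacts (`NULL` = keep in memory only).
#' @param writeImages also write every rendered 2DCOS image to disk.
#' @param seed integer master seed.
#' @return validated list of class `"PipelineConfig"`.
#' @export
pipelineConfig <- function(nPerClass = c(40, 40, 40, 40),
                           partEffect = 0.25, statusEffect = 0.05,
                           noiseSd = 0.002, replicates = 1L,
                           axis = defaultWavenumberAxis(),
                           nBins = 64, fractions = c(0.6, 0.3, 0.1),
                           imageSize = 64, nLevels = 16, colormap = "jet",
                           parts = c("poria", "cutis"),
                           epochs = 50, batchSize = 32, lr = 0.01,
                           weightDecay = 1e-4, momentum = 0.9,
                           channels = c(16, 32, 64),
                           outputDir = NULL, writeImages = FALSE, seed = 1) {
  stopIf(length(fractions) != 3 || abs(sum(fractions) - 1) > 1e-8,
         "fractions must be three numbers summing to 1")
  stopIf(any(nPerClass <= 0), "all class counts must be positive")
  stopIf(length(seed) != 1 || is.na(suppressWarnings(as.integer(seed))),
         "seed must be a single integer")
  stopIf(!all(parts %in% c("poria", "cutis")), "parts must be poria/cutis")
  stopIf(replicates < 1, "replicates must be >= 1")
  # constructing the network config validates lr, weightDecay, imageSize
  resnetConfig(nClasses = 2, inputSize = imageSize, channels = channels,
               lr = lr, weightDecay = weightDecay, momentum = momentum,
               epochs = epochs, batchSize = batchSize, seed = 1)
  structure(as.list(environment()), class = "PipelineConfig")
}

#' Read a pipeline configuration from a YAML file
#'
#' Keys mirror the arguments of [pipelineConfig()]; unknown keys are
#' rejected. Values given in the file override the defaults.
#'
#' @param path YAML file.
#' @return a `"PipelineConfig"`.
#' @export
readPipelineConfig <- function(path) {
  stopIf(!file.exists(path), "config file not found: ", path)
  vals <- yaml::read_yaml(path)
  known <- names(formals(pipelineConfig))
  bad <- setdiff(names(vals), known)
  stopIf(length(bad) > 0, "unknown config key(s): ", paste(bad, collapse = ", "))
  do.call(pipelineConfig, vals)
}

# Render every sample of a binned collection against a reference spectrum
# and stack into a classifier tensor.
renderSampleImages <- function(binned, reference, config, dir = NULL) {
  A <- absorbance(binned)
  wn <- wavenumbers(binned)
  n <- ncol(A)
  out <- array(NA_real_, c(3, config$imageSize, config$imageSize, n))
  files <- character(0)
  for (i in seq_len(n)) {
    m <- perSampleSyncMap(A[, i], reference, wavenumber = wn)
    f <- if (!is.null(dir))
      file.path(dir, paste0(colnames(A)[i], ".png")) else NULL
    img <- renderMap(m, sizePx = config$imageSize, nLevels = config$nLevels,
                     colormap = config$colormap, file = f)
    out[, , , i] <- mapImageTensor(img)
    if (!is.null(f)) files <- c(files, f)
  }
  list(tensor = out, files = files)
}

# Kennard-Stone split of every part stratum; the 2DCOS reference is the
# mean spectrum of the pooled modeling (train + test) samples of all parts,
# so per-sample deviations retain both the part offset and the status
# signal (a per-part reference would make the two status classes mirror
# deviations, which the sign-invariant rank-1 map cannot distinguish).
splitAllParts <- function(binned, config) {
  cd <- SummarizedExperiment::colData(binned)
  splits <- list()
  for (p in unique(cd$part)) {
    keep <- which(cd$part == p)
    sub <- binned[, keep]
    sp <- splitDataset(t(absorbance(sub)),
                       labels = SummarizedExperiment::colData(sub)$status,
                       fractions = config$fractions)
    splits[[p]] <- list(indices = keep, split = sp)
  }
  modeling <- unlist(lapply(splits, function(s)
    s$indices[c(s$split$train, s$split$test)]))
  list(splits = splits,
       reference = rowMeans(absorbance(binned)[, modeling, drop = FALSE]))
}

trainPartModel <- function(binned, part, config, partSplit, reference) {
  sub <- binned[, partSplit$indices]
  status <- SummarizedExperiment::colData(sub)$status
  split <- partSplit$split
  imgDir <- NULL
  if (config$writeImages && !is.null(config$outputDir)) {
    imgDir <- file.path(config$outputDir, paste0("images_", part))
    dir.create(imgDir, recursive = TRUE, showWarnings = FALSE)
  }
  imgs <- renderSampleImages(sub, reference, config, imgDir)
  X <- imgs$tensor
  net <- resnetConfig(nClasses = 2, inputSize = config$imageSize,
                      channels = config$channels, lr = config$lr,
                      weightDecay = config$weightDecay,
                      momentum = config$momentum, epochs = config$epochs,
                      batchSize = config$batchSize,
                      seed = childSeed(config$seed, match(part, c("poria", "cutis"))))
  fit <- trainResnet(buildResnet(net),
                     X[, , , split$train, drop = FALSE], status[split$train],
                     X[, , , split$test, drop = FALSE], status[split$test])
  evTest <- evaluateModel(fit, X[, , , split$test, drop = FALSE],
                          status[split$test])
  evExt <- evaluateModel(fit, X[, , , split$external, drop = FALSE],
                         status[split$external])
  list(part = part, fit = fit, split = split,
       sizes = c(train = length(split$train), test = length(split$test),
                 external = length(split$external)),
       trainAccuracy = utils::tail(fit$history$train_accuracy, 1),
       testAccuracy = evTest$accuracy, externalAccuracy = evExt$accuracy,
       testReport = evTest, externalReport = evExt, files = imgs$files)
}

#' Run the full pipeline
#'
#' Executes simulate -> (average replicates) -> bin -> per-part
#' [splitDataset()] -> per-sample synchronous 2DCOS images -> per-part
#' 12-layer ResNet training -> evaluation on the test and external sets,
#' and assembles a manifest (seed, package version, per-stage metrics,
#' written files with MD5 hashes) that makes the run reproducible. With
#' `dryRun = TRUE` the configuration is validated and the planned stages
#' reported without touching the filesystem or computing anything.
#'
#' @param config a `"PipelineConfig"`.
#' @param dryRun validate only.
#' @return invisibly, a list with `manifest` and (unless dry) `results`
#'   (per-part fits and reports) and `spectra`.
#' @export
runPipeline <- function(config = pipelineConfig(), dryRun = FALSE) {
  stopIf(!inherits(config, "PipelineConfig"),
         "config must come from pipelineConfig()")
  stages <- c("simulate", if (config$replicates > 1) "average-replicates",
              "bin", "split", "2dcos-images",
              paste0("train-", config$parts), "evaluate")
  if (dryRun)
    return(invisible(list(manifest = list(dryRun = TRUE, stages = stages,
                                          seed = config$seed))))
  stage <- "simulate"
  result <- tryCatch({
    profiles <- defaultClassProfiles(config$partEffect, config$statusEffect,
                                     config$noiseSd)
    spectra <- generateDataset(profiles, config$nPerClass, config$axis,
                               seed = childSeed(config$seed, 0),
                               replicates = config$replicates)
    if (config$replicates > 1) {
      stage <- "average-replicates"
      spectra <- averageReplicates(spectra)
    }
    stage <- "bin"
    binned <- binSpectra(spectra, config$nBins)
    stage <- "split"
    sp <- splitAllParts(binned, config)
    parts <- list()
    for (p in config$parts) {
      stage <- paste0("train-", p)
      parts[[p]] <- trainPartModel(binned, p, config, sp$splits[[p]],
                                   sp$reference)
    }
    stage <- "report"
    files <- unlist(lapply(parts, `[[`, "files"))
    metrics <- lapply(parts, function(r)
      list(sizes = as.list(r$sizes),
           trainAccuracy = r$trainAccuracy,
           testAccuracy = r$testAccuracy,
           externalAccuracy = r$externalAccuracy))
    if (!is.null(config$outputDir)) {
      dir.create(config$outputDir, recursive = TRUE, showWarnings = FALSE)
      for (p in names(parts)) {
        hf <- file.path(config$outputDir, paste0("history_", p, ".csv"))
        utils::write.csv(parts[[p]]$fit$history, hf, row.names = FALSE)
        cf <- file.path(config$outputDir, paste0("confusion_", p, ".csv"))
        utils::write.csv(as.data.frame(parts[[p]]$testReport$confusion), cf,
                         row.names = FALSE)
        files <- c(files, hf, cf)
      }
    }
    manifest <- list(
      package = as.character(utils::packageVersion("poriaNIR")),
      seed = config$seed,
      stages = stages,
      metrics = metrics,
      files = if (length(files))
        data.frame(path = files, md5 = unname(tools::md5sum(files)))
      else data.frame(path = character(), md5 = character())
    )
    if (!is.null(config$outputDir)) {
      mf <- file.path(config$outputDir, "manifest.json")
      jsonlite::write_json(manifest, mf, auto_unbox = TRUE, digits = NA)
    }
    list(manifest = manifest, results = parts, spectra = spectra)
  }, error = function(e) {
    stop("pipeline failed at stage '", stage, "': ", conditionMessage(e),
         call. = FALSE)
  })
  invisible(result)
}
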