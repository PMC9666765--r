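# The 12-layer residual CNN: a convolutional stem, two convolution residual
# blocks (projection shortcut where the shape changes) interleaved with
# three identity blocks (identity shortcut), global average pooling and a
# fully-connected softmax head. Counting the main-path weighted layers
# (stem conv + 10 block convs + fully-connected) gives depth 12, the same
# convention by which ResNet-18 counts 18; 1x1 projection shortcuts are not
# counted. Trained with SGD (momentum, L2 weight decay) on the softmax
# cross-entropy.

#' Residual-network configuration
#'
#' Architecture and optimization hyperparameters. The defaults follow the
#' study conditions: SGD with learning rate 0.01, weight-decay coefficient
#' 0.0001, cross-entropy loss, batch normalization after every convolution,
#' ReLU activations, at most 50 epochs. Kernel sizes, channel widths,
#' momentum, batch size and input resolution are free parameters with
#' documented defaults.
#'
#' @param nClasses number of classes (>= 2).
#' @param inputSize input image side in pixels; must survive the stride
#'   plan (divisible by 8).
#' @param inChannels input channels (3 for RGB contour images).
#' @param channels widths after the stem and the two down-sampling stages.
#' @param lr SGD learning rate (> 0).
#' @param weightDecay L2 penalty coefficient lambda (>= 0).
#' @param momentum SGD momentum.
#' @param epochs training epochs.
#' @param batchSize mini-batch size.
#' @param seed integer seed fixing weight initialization and data order.
#' @return list of class `"ResNetConfig"`.
#' @export
resnetConfig <- function(nClasses = 2, inputSize = 64, inChannels = 3,
                         channels = c(16, 32, 64), lr = 0.01,
                         weightDecay = 1e-4, momentum = 0.9, epochs = 50,
                         batchSize = 32, seed = 1) {
  stopIf(lr <= 0, "learning rate must be > 0")
  stopIf(weightDecay < 0, "weight decay must be >= 0")
  stopIf(nClasses < 2, "need at least 2 classes")
  stopIf(length(channels) != 3, "channels must give 3 stage widths")
  s <- inputSize
  stages <- c("stem max-pool", "convolution residual block 1",
              "convolution residual block 2")
  for (st in stages) {
    stopIf(s %% 2 != 0, "inputSize ", inputSize,
           " is incompatible with the stride plan at the ", st)
    s <- s / 2
  }
  structure(list(nClasses = as.integer(nClasses), inputSize = as.integer(inputSize),
                 inChannels = as.integer(inChannels), channels = as.integer(channels),
                 lr = lr, weightDecay = weightDecay, momentum = momentum,
                 epochs = as.integer(epochs), batchSize = as.integer(batchSize),
                 seed = as.integer(seed)),
            class = "ResNetConfig")
}

heConv <- function(cout, cin, k) {
  array(rnorm(cout * cin * k * k, sd = sqrt(2 / (cin * k * k))),
        c(cout, cin, k, k))
}

newBNParams <- function(c) list(gamma = rep(1, c), beta = rep(0, c))
newBNStats <- function(c) list(mean = rep(0, c), var = rep(1, c))

#' Build the 12-layer residual network
#'
#' Layer plan for the default 64 px input: 3x3 stem conv (-> channels[1]),
#' BN, ReLU, 2x2 max pool; convolution residual block (stride 2, ->
#' channels[2]); two identity blocks; convolution residual block (stride 2,
#' -> channels[3]); one identity block; global average pooling;
#' fully-connected softmax head. Weight initialization is He-scaled and
#' fully seeded.
#'
#' @param config a [resnetConfig()].
#' @return list of class `"ResNetModel"` with elements `config`, `params`,
#'   `rs` (batch-norm running statistics), `arch`, `classes` (set by
#'   [trainResnet()]) and `nParameters`.
#' @export
buildResnet <- function(config = resnetConfig()) {
  ch <- config$channels
  arch <- list(
    list(type = "down", stride = 2L, cin = ch[1], cout = ch[2]),
    list(type = "id",   stride = 1L, cin = ch[2], cout = ch[2]),
    list(type = "id",   stride = 1L, cin = ch[2], cout = ch[2]),
    list(type = "down", stride = 2L, cin = ch[2], cout = ch[3]),
    list(type = "id",   stride = 1L, cin = ch[3], cout = ch[3])
  )
  withSeed(config$seed, {
    params <- list(
      stem = list(W = heConv(ch[1], config$inChannels, 3L), b = rep(0, ch[1])),
      bnS = newBNParams(ch[1]),
      blocks = lapply(arch, function(a) {
        bl <- list(
          conv1 = list(W = heConv(a$cout, a$cin, 3L), b = rep(0, a$cout)),
          bn1 = newBNParams(a$cout),
          conv2 = list(W = heConv(a$cout, a$cout, 3L), b = rep(0, a$cout)),
          bn2 = newBNParams(a$cout))
        if (a$type == "down") {
          bl$proj <- list(W = heConv(a$cout, a$cin, 1L), b = rep(0, a$cout))
          bl$bnp <- newBNParams(a$cout)
        }
        bl
      }),
      fc = list(W = matrix(rnorm(config$nClasses * ch[3],
                                 sd = sqrt(2 / ch[3])),
                           config$nClasses, ch[3]),
                b = rep(0, config$nClasses))
    )
  })
  rs <- list(bnS = newBNStats(ch[1]),
             blocks = lapply(arch, function(a)
               if (a$type == "down")
                 list(bn1 = newBNStats(a$cout), bn2 = newBNStats(a$cout),
                      bnp = newBNStats(a$cout))
               else list(bn1 = newBNStats(a$cout), bn2 = newBNStats(a$cout))))
  model <- structure(list(config = config, params = params, rs = rs,
                          arch = arch, classes = NULL), class = "ResNetModel")
  model$nParameters <- length(unlist(params))
  model
}

#' Number of weighted layers on the main path
#'
#' Stem convolution + two convolutions per residual block + the
#' fully-connected head; projection shortcuts are not counted, following
#' the usual ResNet depth-naming convention.
#'
#' @param model a `"ResNetModel"`.
#' @return integer layer count (12 for this architecture).
#' @export
countWeightedLayers <- function(model) {
  1L + 2L * length(model$params$blocks) + 1L
}

# Full forward pass. training = TRUE also returns layer caches and updated
# running statistics.
resnetForward <- function(model, x, training = FALSE) {
  p <- model$params; rs <- model$rs
  cv <- convForward(x, p$stem$W, p$stem$b, 1L, 1L)
  bn <- bnForward(cv$out, p$bnS$gamma, p$bnS$beta, rs$bnS, training)
  rs$bnS <- bn$rs
  rl <- reluForward(bn$out)
  pl <- maxPoolForward(rl$out)
  h <- pl$out
  caches <- list(stem = list(cv = cv$cache, bn = bn$cache, mask = rl$mask,
                             pool = pl$cache),
                 blocks = vector("list", length(p$blocks)))
  for (i in seq_along(p$blocks)) {
    bl <- p$blocks[[i]]; a <- model$arch[[i]]; rb <- rs$blocks[[i]]
    c1 <- convForward(h, bl$conv1$W, bl$conv1$b, a$stride, 1L)
    b1 <- bnForward(c1$out, bl$bn1$gamma, bl$bn1$beta, rb$bn1, training)
    rb$bn1 <- b1$rs
    r1 <- reluForward(b1$out)
    c2 <- convForward(r1$out, bl$conv2$W, bl$conv2$b, 1L, 1L)
    b2 <- bnForward(c2$out, bl$bn2$gamma, bl$bn2$beta, rb$bn2, training)
    rb$bn2 <- b2$rs
    if (a$type == "down") {
      pj <- convForward(h, bl$proj$W, bl$proj$b, a$stride, 0L)
      bp <- bnForward(pj$out, bl$bnp$gamma, bl$bnp$beta, rb$bnp, training)
      rb$bnp <- bp$rs
      sc <- bp$out
      scCache <- list(pj = pj$cache, bp = bp$cache)
    } else {
      sc <- h
      scCache <- NULL
    }
    s <- b2$out + sc
    ro <- reluForward(s)
    rs$blocks[[i]] <- rb
    caches$blocks[[i]] <- list(c1 = c1$cache, b1 = b1$cache, m1 = r1$mask,
                               c2 = c2$cache, b2 = b2$cache, sc = scCache,
                               mOut = ro$mask)
    h <- ro$out
  }
  gp <- globalAvgPoolForward(h)
  fc <- fcForward(gp$out, p$fc$W, p$fc$b)
  caches$gapDim <- gp$inDim
  caches$fc <- fc
  list(logits = fc$out, caches = caches, rs = rs)
}

resnetBackward <- function(model, caches, dlogits) {
  p <- model$params
  fcb <- fcBackward(dlogits, p$fc$W, caches$fc)
  grads <- list(fc = list(W = fcb$dW, b = fcb$db))
  dh <- globalAvgPoolBackward(fcb$dx, caches$gapDim)
  grads$blocks <- vector("list", length(p$blocks))
  for (i in rev(seq_along(p$blocks))) {
    bl <- p$blocks[[i]]; a <- model$arch[[i]]; cc <- caches$blocks[[i]]
    ds <- reluBackward(dh, cc$mOut)
    b2b <- bnBackward(ds, cc$b2)
    c2b <- convBackward(b2b$dx, bl$conv2$W, cc$c2)
    dr1 <- reluBackward(c2b$dx, cc$m1)
    b1b <- bnBackward(dr1, cc$b1)
    c1b <- convBackward(b1b$dx, bl$conv1$W, cc$c1)
    g <- list(conv1 = list(W = c1b$dW, b = c1b$db),
              bn1 = list(gamma = b1b$dgamma, beta = b1b$dbeta),
              conv2 = list(W = c2b$dW, b = c2b$db),
              bn2 = list(gamma = b2b$dgamma, beta = b2b$dbeta))
    if (a$type == "down") {
      bpb <- bnBackward(ds, cc$sc$bp)
      pjb <- convBackward(bpb$dx, bl$proj$W, cc$sc$pj)
      g$proj <- list(W = pjb$dW, b = pjb$db)
      g$bnp <- list(gamma = bpb$dgamma, beta = bpb$dbeta)
      dsc <- pjb$dx
    } else {
      dsc <- ds
    }
    dh <- c1b$dx + dsc
    grads$blocks[[i]] <- g
  }
  pb <- maxPoolBackward(dh, caches$stem$pool)
  drl <- reluBackward(pb, caches$stem$mask)
  bnb <- bnBackward(drl, caches$stem$bn)
  cvb <- convBackward(bnb$dx, p$stem$W, caches$stem$cv)
  grads$stem <- list(W = cvb$dW, b = cvb$db)
  grads$bnS <- list(gamma = bnb$dgamma, beta = bnb$dbeta)
  grads
}

# SGD with momentum; L2 weight decay applied to convolution / FC kernels
# (leaves named "W") only, as is standard.
sgdUpdate <- function(params, grads, vel, lr, momentum, wd) {
  nms <- names(params)
  keys <- if (is.null(nms)) seq_along(params) else nms
  for (key in keys) {
    if (is.list(params[[key]])) {
      r <- sgdUpdate(params[[key]], grads[[key]], vel[[key]], lr, momentum, wd)
      params[[key]] <- r$params
      vel[[key]] <- r$vel
    } else {
      g <- grads[[key]]
      if (identical(key, "W")) g <- g + wd * params[[key]]
      vel[[key]] <- momentum * vel[[key]] - lr * g
      params[[key]] <- params[[key]] + vel[[key]]
    }
  }
  list(params = params, vel = vel)
}

zeroLike <- function(x) {
  if (is.list(x)) lapply(x, zeroLike)
  else x * 0
}

labelsToIdx <- function(y, classes) {
  idx <- match(as.character(y), classes)
  stopIf(anyNA(y) || anyNA(idx), "label(s) outside the training classes: ",
         paste(unique(as.character(y)[is.na(idx)]), collapse = ", "))
  idx
}

checkImageTensor <- function(x, config) {
  stopIf(length(dim(x)) != 4, "images must form a (C, H, W, N) array")
  d <- dim(x)
  stopIf(d[1] != config$inChannels || d[2] != config$inputSize ||
           d[3] != config$inputSize,
         "image tensor is ", d[1], "x", d[2], "x", d[3],
         " but the model expects ", config$inChannels, "x",
         config$inputSize, "x", config$inputSize)
  invisible(d[4])
}

evalLogits <- function(model, x) {
  n <- dim(x)[4]
  bs <- model$config$batchSize
  out <- matrix(NA_real_, model$config$nClasses, n)
  for (start in seq(1, n, by = bs)) {
    j <- start:min(start + bs - 1, n)
    out[, j] <- resnetForward(model, x[, , , j, drop = FALSE],
                              training = FALSE)$logits
  }
  out
}

#' Train the residual network
#'
#' Minimizes the softmax cross-entropy plus the L2 penalty
#' `weightDecay/2 * ||W||^2` by mini-batch SGD with momentum. Weight
#' initialization and the per-epoch shuffle are fully seeded, so a fixed
#' seed reproduces the run exactly. After every epoch, accuracy and plain
#' cross-entropy loss are recorded on the training set and (when given) the
#' test set, evaluated in inference mode.
#'
#' @param model a fresh [buildResnet()] model.
#' @param trainX images as a (channels, height, width, n) array; see
#'   [stackMapImages()].
#' @param trainY class labels, length n; at least two distinct classes.
#' @param testX,testY optional held-out set monitored per epoch.
#' @param epochs number of epochs (default from the model config).
#' @return list of class `"ResnetFit"`: `model` (trained, with `classes`
#'   set) and `history` (data.frame with `epoch`, `train_accuracy`,
#'   `test_accuracy`, `train_loss`, `test_loss`).
#' @export
trainResnet <- function(model, trainX, trainY, testX = NULL, testY = NULL,
                        epochs = NULL) {
  cfg <- model$config
  n <- checkImageTensor(trainX, cfg)
  stopIf(n == 0 || length(trainY) != n,
         "trainY length must match the number of images")
  classes <- sort(unique(as.character(trainY)))
  stopIf(length(classes) < 2, "training set holds a single class")
  stopIf(length(classes) > cfg$nClasses, "more classes than config$nClasses")
  model$classes <- classes
  y <- labelsToIdx(trainY, classes)
  if (!is.null(testX)) checkImageTensor(testX, cfg)
  if (is.null(epochs)) epochs <- cfg$epochs
  vel <- zeroLike(model$params)
  hist <- vector("list", epochs)
  for (ep in seq_len(epochs)) {
    ord <- withSeed(childSeed(cfg$seed, ep), sample.int(n))
    for (start in seq(1, n, by = cfg$batchSize)) {
      j <- ord[start:min(start + cfg$batchSize - 1, n)]
      fwd <- resnetForward(model, trainX[, , , j, drop = FALSE],
                           training = TRUE)
      model$rs <- fwd$rs
      ce <- softmaxCrossEntropy(fwd$logits, y[j])
      grads <- resnetBackward(model, fwd$caches, ce$dlogits)
      upd <- sgdUpdate(model$params, grads, vel, cfg$lr, cfg$momentum,
                       cfg$weightDecay)
      model$params <- upd$params
      vel <- upd$vel
    }
    trEval <- evalSet(model, trainX, y)
    teEval <- if (!is.null(testX))
      evalSet(model, testX, labelsToIdx(testY, classes))
    else list(accuracy = NA_real_, loss = NA_real_)
    hist[[ep]] <- data.frame(epoch = ep,
                             train_accuracy = trEval$accuracy,
                             test_accuracy = teEval$accuracy,
                             train_loss = trEval$loss,
                             test_loss = teEval$loss)
  }
  structure(list(model = model, history = do.call(rbind, hist)),
            class = "ResnetFit")
}

evalSet <- function(model, x, yIdx) {
  logits <- evalLogits(model, x)
  p <- softmaxProbs(logits)
  pred <- apply(logits, 2, which.max)
  list(accuracy = mean(pred == yIdx),
       loss = -mean(log(pmax(p[cbind(yIdx, seq_along(yIdx))], 1e-12))))
}

#' Evaluate a trained model
#'
#' Computes the confusion matrix (true x predicted counts), overall
#' accuracy (trace / total) and per-class recall on a labelled set; no
#' parameters are updated.
#'
#' @param model a trained `"ResNetModel"` (or a `"ResnetFit"`).
#' @param x image tensor (C, H, W, n).
#' @param y true labels; must be drawn from the training classes.
#' @return list of class `"EvalReport"`: `confusion`, `accuracy`, `recall`.
#' @export
evaluateModel <- function(model, x, y) {
  if (inherits(model, "ResnetFit")) model <- model$model
  stopIf(is.null(model$classes), "model has not been trained")
  checkImageTensor(x, model$config)
  yIdx <- labelsToIdx(y, model$classes)
  pred <- apply(evalLogits(model, x), 2, which.max)
  k <- length(model$classes)
  confusion <- table(true = factor(model$classes[yIdx], model$classes),
                     predicted = factor(model$classes[pred], model$classes))
  acc <- sum(diag(confusion)) / sum(confusion)
  recall <- diag(confusion) / pmax(rowSums(confusion), 1)
  structure(list(confusion = confusion, accuracy = acc, recall = recall),
            class = "EvalReport")
}

#' Predict class probabilities for one image
#'
#' @param model a trained `"ResNetModel"` (or `"ResnetFit"`).
#' @param image array (C, H, W) or (H, W, C) matching the model input size.
#' @return list with `probabilities` (named, summing to 1) and `label`
#'   (argmax; ties resolve to the lowest class index).
#' @export
predictModel <- function(model, image) {
  if (inherits(model, "ResnetFit")) model <- model$model
  cfg <- model$config
  d <- dim(image)
  stopIf(length(d) != 3, "image must be a 3-d array")
  if (d[1] != cfg$inChannels && d[3] == cfg$inChannels)
    image <- aperm(image, c(3, 1, 2))
  d <- dim(image)
  stopIf(d[1] != cfg$inChannels || d[2] != cfg$inputSize ||
           d[3] != cfg$inputSize,
         "image shape ", paste(d, collapse = "x"),
         " does not match the model input ", cfg$inChannels, "x",
         cfg$inputSize, "x", cfg$inputSize)
  x <- array(image, c(d, 1))
  probs <- drop(softmaxProbs(resnetForward(model, x, FALSE)$logits))
  cls <- if (is.null(model$classes)) as.character(seq_along(probs))
         else model$classes
  names(probs) <- cls
  list(probabilities = probs, label = cls[which.max(probs)])
}

#' Stack rendered map images into a classifier tensor
#'
#' @param images list of `"MapImage"` objects (from [renderMap()]) sharing
#'   one size.
#' @return array (3, size, size, n).
#' @export
stackMapImages <- function(images) {
  stopIf(length(images) == 0, "no images")
  sz <- images[[1]]$sizePx
  out <- array(NA_real_, c(3, sz, sz, length(images)))
  for (i in seq_along(images)) out[, , , i] <- mapImageTensor(images[[i]])
  out
}

#' Plot training curves
#'
#' Accuracy and loss per epoch for the training and test sets.
#'
#' @param history the `history` of a `"ResnetFit"`.
#' @param file optional PNG path.
#' @return a ggplot object.
#' @export
plotHistory <- function(history, file = NULL) {
  long <- rbind(
    data.frame(epoch = history$epoch, value = history$train_accuracy,
               metric = "accuracy", set = "train"),
    data.frame(epoch = history$epoch, value = history$test_accuracy,
               metric = "accuracy", set = "test"),
    data.frame(epoch = history$epoch, value = history$train_loss,
               metric = "loss", set = "train"),
    data.frame(epoch = history$epoch, value = history$test_loss,
               metric = "loss", set = "test"))
  gg <- ggplot2::ggplot(long, ggplot2::aes(.data$epoch, .data$value,
                                           colour = .data$set)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, gg, width = 7, height = 3.5, dpi = 150)
    return(invisible(gg))
  }
  gg
}
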