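# Layer-level and model-level checks of the residual network. The analytic
# backward pass is verified against central finite differences, and the
# residual identity, softmax normalization and the 12-weighted-layer count
# are asserted structurally.

pn <- asNamespace("poriaNIR")

tinyConfig <- function(...) {
  resnetConfig(nClasses = 2, inputSize = 16, channels = c(4, 6, 8),
               batchSize = 4, seed = 7, ...)
}

test_that("analytic gradients match finite differences through every layer type", {
  set.seed(42)
  m <- buildResnet(tinyConfig())
  x <- array(rnorm(3 * 16 * 16 * 4), c(3, 16, 16, 4))
  y <- c(1, 2, 1, 2)
  lossOf <- function(model) {
    f <- pn$resnetForward(model, x, training = TRUE)
    pn$softmaxCrossEntropy(f$logits, y)$loss
  }
  f <- pn$resnetForward(m, x, training = TRUE)
  gr <- pn$resnetBackward(m, f$caches,
                          pn$softmaxCrossEntropy(f$logits, y)$dlogits)
  eps <- 1e-5
  checkOne <- function(get, set, gAna) {
    m1 <- m; m1$params <- set(m1$params, get(m1$params) + eps)
    m2 <- m; m2$params <- set(m2$params, get(m2$params) - eps)
    num <- (lossOf(m1) - lossOf(m2)) / (2 * eps)
    expect_lt(abs(num - gAna) / max(1e-8, abs(num) + abs(gAna)), 1e-5)
  }
  # stem conv kernel, stem BN scale, projection shortcut, a deep conv, head
  checkOne(function(p) p$stem$W[5],
           function(p, v) { p$stem$W[5] <- v; p }, gr$stem$W[5])
  checkOne(function(p) p$bnS$gamma[2],
           function(p, v) { p$bnS$gamma[2] <- v; p }, gr$bnS$gamma[2])
  checkOne(function(p) p$blocks[[1]]$proj$W[3],
           function(p, v) { p$blocks[[1]]$proj$W[3] <- v; p },
           gr$blocks[[1]]$proj$W[3])
  checkOne(function(p) p$blocks[[4]]$conv2$W[11],
           function(p, v) { p$blocks[[4]]$conv2$W[11] <- v; p },
           gr$blocks[[4]]$conv2$W[11])
  checkOne(function(p) p$fc$W[3],
           function(p, v) { p$fc$W[3] <- v; p }, gr$fc$W[3])
})

test_that("the network counts 12 weighted layers on the main path", {
  m <- buildResnet(tinyConfig())
  expect_equal(countWeightedLayers(m), 12L)
  # structure: 2 convolution residual blocks + 3 identity blocks
  types <- vapply(m$arch, `[[`, "", "type")
  expect_equal(sum(types == "down"), 2L)
  expect_equal(sum(types == "id"), 3L)
})

test_that("an identity block with zero residual weights is the identity map", {
  set.seed(3)
  m <- buildResnet(tinyConfig())
  bl <- m$params$blocks[[2]]  # an identity block
  bl$conv1$W[] <- 0; bl$conv1$b[] <- 0
  bl$conv2$W[] <- 0; bl$conv2$b[] <- 0
  bl$bn1$gamma[] <- 0; bl$bn1$beta[] <- 0
  bl$bn2$gamma[] <- 0; bl$bn2$beta[] <- 0
  x <- array(abs(rnorm(6 * 8 * 8 * 2)), c(6, 8, 8, 2))  # post-ReLU: x >= 0
  rs <- list(bn1 = list(mean = rep(0, 6), var = rep(1, 6)),
             bn2 = list(mean = rep(0, 6), var = rep(1, 6)))
  c1 <- pn$convForward(x, bl$conv1$W, bl$conv1$b, 1L, 1L)
  b1 <- pn$bnForward(c1$out, bl$bn1$gamma, bl$bn1$beta, rs$bn1, TRUE)
  r1 <- pn$reluForward(b1$out)
  c2 <- pn$convForward(r1$out, bl$conv2$W, bl$conv2$b, 1L, 1L)
  b2 <- pn$bnForward(c2$out, bl$bn2$gamma, bl$bn2$beta, rs$bn2, TRUE)
  out <- pn$reluForward(b2$out + x)$out
  expect_equal(out, x)
})

test_that("forward pass yields a probability vector summing to one", {
  set.seed(9)
  m <- buildResnet(tinyConfig())
  img <- array(rnorm(3 * 16 * 16), c(3, 16, 16))
  pr <- predictModel(m, img)
  expect_true(all(pr$probabilities >= 0 & pr$probabilities <= 1))
  expect_lt(abs(sum(pr$probabilities) - 1), 1e-6)
  # identical input, identical output
  expect_identical(pr$probabilities, predictModel(m, img)$probabilities)
  # zeroed head: uniform probabilities
  m0 <- m
  m0$params$fc$W[] <- 0; m0$params$fc$b[] <- 0
  expect_equal(unname(predictModel(m0, img)$probabilities), c(0.5, 0.5))
  # channel-last input is accepted, wrong sizes are not
  expect_equal(predictModel(m, aperm(img, c(2, 3, 1)))$probabilities,
               pr$probabilities)
  expect_error(predictModel(m, array(0, c(3, 8, 8))), "does not match")
})

test_that("input sizes incompatible with the stride plan name the layer", {
  expect_error(resnetConfig(inputSize = 20), "convolution residual block 2")
  expect_error(resnetConfig(inputSize = 17), "stem max-pool")
})

separableImages <- function(nPer = 8, size = 16, seed = 5) {
  set.seed(seed)
  base1 <- array(0, c(3, size, size)); base1[, 1:(size / 2), ] <- 1
  base2 <- array(0, c(3, size, size)); base2[, , 1:(size / 2)] <- 1
  X <- array(0, c(3, size, size, 2 * nPer))
  for (i in seq_len(nPer)) {
    X[, , , i] <- base1 + rnorm(length(base1), sd = 0.05)
    X[, , , nPer + i] <- base2 + rnorm(length(base2), sd = 0.05)
  }
  list(X = X, y = rep(c("left", "top"), each = nPer))
}

test_that("training separates two well-separated classes and decreases loss", {
  d <- separableImages()
  cfg <- tinyConfig(epochs = 12)
  fit <- trainResnet(buildResnet(cfg), d$X, d$y)
  h <- fit$history
  expect_equal(nrow(h), 12)
  expect_true(all(h$train_accuracy >= 0 & h$train_accuracy <= 1))
  expect_true(all(h$train_loss >= 0))
  expect_equal(h$train_accuracy[nrow(h)], 1)
  # optimization sanity: the loss trends downward
  expect_lt(mean(tail(h$train_loss, 3)), mean(head(h$train_loss, 3)))
})

test_that("training is reproducible when the seed fixes init and shuffle", {
  d <- separableImages(nPer = 4)
  cfg <- tinyConfig(epochs = 3)
  f1 <- trainResnet(buildResnet(cfg), d$X, d$y)
  f2 <- trainResnet(buildResnet(cfg), d$X, d$y)
  expect_identical(f1$history, f2$history)
})

test_that("degenerate training sets are rejected", {
  d <- separableImages(nPer = 4)
  cfg <- tinyConfig(epochs = 1)
  expect_error(trainResnet(buildResnet(cfg), d$X, rep("left", 8)),
               "single class")
  expect_error(trainResnet(buildResnet(cfg), d$X, d$y[1:3]), "length")
  expect_error(trainResnet(buildResnet(cfg), array(0, c(3, 8, 8, 2)),
                           c("a", "b")), "expects")
})

test_that("evaluation reports a coherent confusion matrix", {
  d <- separableImages(nPer = 6)
  cfg <- tinyConfig(epochs = 10)
  fit <- trainResnet(buildResnet(cfg), d$X, d$y)
  ev <- evaluateModel(fit, d$X, d$y)
  expect_equal(sum(ev$confusion), 12)
  expect_equal(ev$accuracy, sum(diag(ev$confusion)) / sum(ev$confusion))
  expect_equal(unname(rowSums(ev$confusion)), c(6, 6))
  # perfect predictions give a diagonal matrix and accuracy 1
  if (ev$accuracy == 1) expect_true(all(ev$confusion[1, 2] == 0 &&
                                          ev$confusion[2, 1] == 0))
  # a constant predictor scores 0.5 on a balanced two-class set
  m0 <- fit$model
  m0$params$fc$W[] <- 0; m0$params$fc$b[] <- 0
  ev0 <- evaluateModel(m0, d$X, d$y)
  expect_equal(ev0$accuracy, 0.5)
  # labels outside the training classes are rejected
  expect_error(evaluateModel(fit, d$X, rep("elsewhere", 12)),
               "outside the training classes")
})
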