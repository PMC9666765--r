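# Kennard-Stone partitioning and PCA score visualization.

#' Kennard-Stone design-point selection
#'
#' Deterministic max-min selection in Euclidean feature space: the first two
#' picks are the pair at maximal distance; each later pick maximizes its
#' minimum distance to the already-selected set. Ties are broken toward the
#' lowest row index (for the initial pair: smallest first index, then
#' smallest second), so the output is reproducible, and duplicate rows are
#' allowed.
#'
#' @param X numeric matrix, samples in rows.
#' @param k number of points to select (2 <= k <= nrow(X)).
#' @return integer vector of selected row indices, in pick order.
#' @examples
#' kennardStone(cbind(c(0, 1, 2, 10)), 3)  # 1 4 3  (points 0, 10, 2)
#' @export
kennardStone <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  stopIf(k < 2, "k must be >= 2")
  stopIf(k > n, "k exceeds the number of samples")
  D <- as.matrix(stats::dist(X))
  ut <- upper.tri(D)
  mx <- max(D[ut])
  cand <- which(D == mx & ut, arr.ind = TRUE)
  cand <- cand[order(cand[, 1], cand[, 2]), , drop = FALSE]
  sel <- c(cand[1, 1], cand[1, 2])
  mind <- pmin(D[, sel[1]], D[, sel[2]])
  mind[sel] <- -Inf
  while (length(sel) < k) {
    nxt <- which.max(mind)  # first max = lowest index on ties
    sel <- c(sel, nxt)
    mind <- pmin(mind, D[, nxt])
    mind[nxt] <- -Inf
  }
  as.integer(unname(sel))
}

largestRemainder <- function(n, fractions) {
  raw <- n * fractions
  base <- floor(raw)
  short <- n - sum(base)
  if (short > 0) {
    ord <- order(-(raw - base), seq_along(fractions))
    base[ord[seq_len(short)]] <- base[ord[seq_len(short)]] + 1
  }
  as.integer(base)
}

#' Train / test / external partition by Kennard-Stone
#'
#' Within each class stratum, Kennard-Stone first selects the most design-
#' space-covering 90% as the modeling data; the unselected complement is the
#' external validation set. A second Kennard-Stone run over the modeling
#' rows selects the training set (2:1 train:test of the modeling data under
#' the default 60/30/10 fractions); the remainder is the test set. Target
#' counts per stratum are rounded by the largest-remainder method so subset
#' sizes sum exactly to n. The whole partition is a deterministic function
#' of the feature rows.
#'
#' @param X numeric feature matrix (samples x features), or an
#'   [NIRSpectra-class] (features = spectra).
#' @param labels class label per row (ignored for the `NIRSpectra` method,
#'   which uses `classLabels`); pass a constant vector for no stratification.
#' @param fractions length-3 numeric (train, test, external) summing to 1.
#' @return list of class `"DatasetSplit"`: integer index vectors `train`,
#'   `test`, `external` (into the rows of `X`), and `fractions`.
#' @export
splitDataset <- function(X, labels = NULL, fractions = c(0.6, 0.3, 0.1)) {
  if (methods::is(X, "NIRSpectra")) {
    labels <- classLabels(X)
    X <- t(absorbance(X))
  }
  X <- as.matrix(X)
  n <- nrow(X)
  if (is.null(labels)) labels <- rep("all", n)
  stopIf(length(fractions) != 3, "fractions must have length 3")
  stopIf(abs(sum(fractions) - 1) > 1e-8, "fractions must sum to 1")
  train <- test <- external <- integer(0)
  for (cl in unique(labels)) {
    rows <- which(labels == cl)
    nc <- length(rows)
    stopIf(nc < 3, "class '", cl, "' has fewer than 3 samples")
    counts <- largestRemainder(nc, fractions)
    nModel <- counts[1] + counts[2]
    model <- if (nModel == nc) seq_len(nc)
             else sort(kennardStone(X[rows, , drop = FALSE], nModel))
    ext <- setdiff(seq_len(nc), model)
    tr <- if (counts[1] == length(model)) model
          else sort(model[kennardStone(X[rows[model], , drop = FALSE],
                                       counts[1])])
    te <- setdiff(model, tr)
    train <- c(train, rows[tr])
    test <- c(test, rows[te])
    external <- c(external, rows[ext])
  }
  structure(list(train = sort(train), test = sort(test),
                 external = sort(external), fractions = fractions),
            class = "DatasetSplit")
}

#' PCA scores and explained variance
#'
#' Column-mean-centered principal component analysis via singular value
#' decomposition ([stats::prcomp]). Explained-variance ratios are component
#' variances over the total variance of all components.
#'
#' @param X numeric matrix, samples in rows.
#' @param nComponents number of components to keep
#'   (<= min(nrow, ncol)).
#' @return list of class `"PCAResult"`: `scores` (n x nComponents),
#'   `explainedVarianceRatio`, `loadings`.
#' @export
pcaScores <- function(X, nComponents = 2) {
  X <- as.matrix(X)
  stopIf(nComponents > min(dim(X)),
         "nComponents exceeds min(n, p) = ", min(dim(X)))
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  tot <- sum(pc$sdev^2)
  if (tot < .Machine$double.eps) {
    warning("matrix has zero total variance; all ratios are 0", call. = FALSE)
    ratio <- rep(0, nComponents)
  } else {
    ratio <- (pc$sdev^2 / tot)[seq_len(nComponents)]
  }
  k <- min(nComponents, ncol(pc$x))
  scores <- pc$x[, seq_len(k), drop = FALSE]
  if (k < nComponents)  # rank-deficient input: pad zero-variance components
    scores <- cbind(scores, matrix(0, nrow(X), nComponents - k))
  structure(list(scores = scores,
                 explainedVarianceRatio = ratio,
                 loadings = pc$rotation[, seq_len(k), drop = FALSE]),
            class = "PCAResult")
}

#' Plot PCA scores with class coloring
#'
#' @param pca a `"PCAResult"`.
#' @param labels class label per sample.
#' @param file optional PNG path.
#' @return a ggplot object (invisibly when written to file).
#' @export
plotScores <- function(pca, labels, file = NULL) {
  df <- data.frame(PC1 = pca$scores[, 1], PC2 = pca$scores[, 2],
                   class = labels)
  r <- pca$explainedVarianceRatio
  gg <- ggplot2::ggplot(df, ggplot2::aes(.data$PC1, .data$PC2,
                                         colour = .data$class)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::labs(x = sprintf("PC1 (%.1f%%)", 100 * r[1]),
                  y = sprintf("PC2 (%.1f%%)", 100 * r[2])) +
    ggplot2::theme_minimal()
  if (!is.null(file)) {
    ggplot2::ggsave(file, gg, width = 5, height = 4, dpi = 150)
    return(invisible(gg))
  }
  gg
}
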