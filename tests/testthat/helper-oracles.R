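# Independent brute-force oracles used to verify the package's fast paths.
# Each is a direct, unoptimized transcription of the definition and shares
# no code with the implementation it checks.

# Synchronous 2DCOS by explicit double loop over wavenumber pairs.
bruteForceSyncMap <- function(dyn) {
  m <- nrow(dyn); p <- ncol(dyn)
  phi <- matrix(NA_real_, p, p)
  for (v1 in seq_len(p))
    for (v2 in seq_len(p))
      phi[v1, v2] <- sum(dyn[, v1] * dyn[, v2]) / (m - 1)
  phi
}

# Kennard-Stone by stepwise enumeration: start at the globally farthest
# pair (lowest indices on ties), then repeatedly scan every unselected
# candidate for the one maximizing its minimum distance to the selection.
bruteForceKennardStone <- function(X, k) {
  X <- as.matrix(X)
  n <- nrow(X)
  d <- function(i, j) sqrt(sum((X[i, ] - X[j, ])^2))
  best <- c(-1, 0, 0)
  for (i in seq_len(n - 1))
    for (j in (i + 1):n)
      if (d(i, j) > best[1]) best <- c(d(i, j), i, j)
  sel <- best[2:3]
  while (length(sel) < k) {
    bestScore <- -1; bestIdx <- NA
    for (cand in seq_len(n)) {
      if (cand %in% sel) next
      score <- min(vapply(sel, function(s) d(cand, s), 0))
      if (score > bestScore) { bestScore <- score; bestIdx <- cand }
    }
    sel <- c(sel, bestIdx)
  }
  sel
}

# PCA via eigendecomposition of the sample covariance matrix.
bruteForcePCA <- function(X) {
  Xc <- sweep(X, 2, colMeans(X))
  ev <- eigen(cov(Xc), symmetric = TRUE)
  list(scores = Xc %*% ev$vectors,
       ratio = ev$values / sum(ev$values))
}

# Greedy Spearman elimination as a literal pair scan.
bruteForceSpearmanFilter <- function(df, threshold = 0.8,
                                     priority = colnames(df)) {
  active <- colnames(df)
  prio <- match(active, priority)
  repeat {
    worst <- NULL; worstRho <- threshold
    for (ai in seq_along(active)) {
      for (bi in seq_along(active)) {
        if (bi <= ai) next
        r <- suppressWarnings(
          cor(df[[active[ai]]], df[[active[bi]]], method = "spearman"))
        if (abs(r) > worstRho) { worstRho <- abs(r); worst <- c(ai, bi) }
      }
    }
    if (is.null(worst)) break
    a <- active[worst[1]]; b <- active[worst[2]]
    loser <- if (prio[worst[1]] <= prio[worst[2]]) b else a
    prio <- prio[active != loser]
    active <- active[active != loser]
  }
  active
}

# Habitat overlay as a cell-wise triple loop.
bruteForceOverlay <- function(cg, sg, veg, suitableClasses) {
  out <- matrix(NA_real_, nrow(cg), ncol(cg))
  for (i in seq_len(nrow(cg))) {
    for (j in seq_len(ncol(cg))) {
      if (is.na(cg[i, j]) || is.na(sg[i, j]) || is.na(veg[i, j])) next
      out[i, j] <- as.numeric(cg[i, j] == 1 && sg[i, j] == 1 &&
                                veg[i, j] %in% suitableClasses)
    }
  }
  out
}

# Small spectral fixture: a handful of samples on a short axis.
tinyAxis <- function(n = 40) seq(4000, 10000, length.out = n)

tinyCollection <- function(n = 4, axisLen = 12, seed = 1) {
  set.seed(seed)
  wn <- seq(4000, 10000, length.out = axisLen)
  A <- matrix(runif(axisLen * n), ncol = n)
  NIRSpectra(A, wn, sampleId = sprintf("s%02d", seq_len(n)),
             classLabel = "wild-poria")
}
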