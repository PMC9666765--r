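test_that("Kennard-Stone picks the documented points on a 1-D example", {
  X <- cbind(c(0, 1, 2, 10))
  expect_equal(kennardStone(X, 3), c(1, 4, 3))  # points 0, 10, 2
  expect_setequal(kennardStone(X, 4), 1:4)      # k = n returns everything
  expect_equal(sort(kennardStone(X, 2)), c(1, 4))  # farthest pair
  expect_error(kennardStone(X, 1), ">= 2")
  expect_error(kennardStone(X, 5), "exceeds")
})

test_that("Kennard-Stone agrees with stepwise enumeration for small n", {
  set.seed(99)
  for (rep in 1:5) {
    n <- sample(4:10, 1)
    X <- matrix(rnorm(n * 2), n, 2)
    for (k in 2:n)
      expect_equal(kennardStone(X, k), bruteForceKennardStone(X, k))
  }
})

test_that("duplicate rows break ties toward the lowest index", {
  X <- cbind(c(0, 0, 5, 5))
  sel <- kennardStone(X, 3)
  expect_equal(sel[1:2], c(1, 3))  # first duplicate of each extreme
  expect_equal(sel[3], 2)          # tie at distance 0: lowest index
})

test_that("the 60/30/10 split is exact, disjoint and exhaustive", {
  set.seed(7)
  X <- matrix(rnorm(100 * 3), 100, 3)
  sp <- splitDataset(X)
  expect_equal(length(sp$train), 60)
  expect_equal(length(sp$test), 30)
  expect_equal(length(sp$external), 10)
  all3 <- c(sp$train, sp$test, sp$external)
  expect_equal(sort(all3), 1:100)
  expect_equal(anyDuplicated(all3), 0L)
})

test_that("stratified split sizes sum to n across uneven classes", {
  set.seed(8)
  n <- c(34, 17, 19, 15)
  X <- matrix(rnorm(sum(n) * 2), sum(n), 2)
  labels <- rep(letters[1:4], n)
  sp <- splitDataset(X, labels)
  expect_equal(length(c(sp$train, sp$test, sp$external)), sum(n))
  for (cl in letters[1:4]) {
    rows <- which(labels == cl)
    expect_gt(length(intersect(sp$train, rows)), 0)
    expect_gt(length(intersect(sp$test, rows)), 0)
    expect_gt(length(intersect(sp$external, rows)), 0)
  }
  expect_error(splitDataset(X[1:5, ], c("a", "a", "b", "b", "b")),
               "fewer than 3")
  expect_error(splitDataset(X, labels, fractions = c(0.6, 0.3, 0.2)),
               "sum to 1")
})

test_that("splitting the full four-class study size is exact and exhaustive", {
  set.seed(30)
  n <- c(347, 165, 175, 152)
  X <- matrix(rnorm(sum(n) * 10), sum(n), 10)
  labels <- rep(c("wp", "cp", "wc", "cc"), n)
  sp <- splitDataset(X, labels)
  expect_equal(length(c(sp$train, sp$test, sp$external)), 839)
  expect_equal(sort(c(sp$train, sp$test, sp$external)), seq_len(839))
  # each subset fraction is within one sample per stratum of its target
  for (cl in unique(labels)) {
    rows <- which(labels == cl)
    got <- c(length(intersect(sp$train, rows)),
             length(intersect(sp$test, rows)),
             length(intersect(sp$external, rows)))
    expect_true(all(abs(got - length(rows) * c(0.6, 0.3, 0.1)) <= 1))
  }
})

test_that("the partition is invariant to row order (by sample identity)", {
  set.seed(21)
  X <- matrix(rnorm(30 * 4), 30, 4)
  ids <- sprintf("s%02d", 1:30)
  labels <- rep(c("a", "b"), each = 15)
  sp1 <- splitDataset(X, labels)
  perm <- sample(30)
  sp2 <- splitDataset(X[perm, ], labels[perm])
  expect_setequal(ids[sp1$train], ids[perm][sp2$train])
  expect_setequal(ids[sp1$test], ids[perm][sp2$test])
  expect_setequal(ids[sp1$external], ids[perm][sp2$external])
})

test_that("PCA matches a covariance eigendecomposition oracle", {
  set.seed(5)
  X <- matrix(rnorm(6 * 4), 6, 4)
  pca <- pcaScores(X, 4)
  oracle <- bruteForcePCA(X)
  expect_equal(pca$explainedVarianceRatio, oracle$ratio[1:4],
               tolerance = 1e-10)
  expect_equal(abs(pca$scores), abs(oracle$scores[, 1:4]),
               tolerance = 1e-10, ignore_attr = TRUE)
})

test_that("PCA scores are orthogonal and ratios behave on edge cases", {
  set.seed(6)
  X <- matrix(rnorm(20 * 5), 20, 5)
  pca <- pcaScores(X, 5)
  G <- crossprod(pca$scores)
  expect_lt(max(abs(G - diag(diag(G)))), 1e-8)
  expect_true(all(diff(pca$explainedVarianceRatio) <= 1e-12))
  expect_lte(sum(pca$explainedVarianceRatio), 1 + 1e-12)
  # collinear data: one component carries everything
  t <- seq(0, 1, length.out = 10)
  line <- cbind(2 * t, -t)
  expect_equal(pcaScores(line, 2)$explainedVarianceRatio[1], 1)
  # constant matrix: zero variance with a warning
  expect_warning(z <- pcaScores(matrix(1, 5, 3), 2), "zero total variance")
  expect_equal(z$explainedVarianceRatio, c(0, 0))
  expect_error(pcaScores(X, 25), "exceeds")
})
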