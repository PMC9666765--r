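test_that("dynamic spectra subtract the reference and center columns", {
  wn <- seq(4000, 10000, length.out = 2)
  sp <- NIRSpectra(cbind(c(1, 3), c(3, 1)), wn, sampleId = c("a", "b"),
                   classLabel = "x")
  dyn <- dynamicSpectra(sp)
  expect_equal(unname(dyn@dyn), rbind(c(-1, 1), c(1, -1)))
  # identical spectra with a mean reference give an all-zero matrix
  same <- NIRSpectra(cbind(c(1, 2), c(1, 2)), wn, sampleId = c("a", "b"),
                     classLabel = "x")
  expect_true(all(dynamicSpectra(same)@dyn == 0))
  # centering identity on arbitrary collections
  sp2 <- tinyCollection(n = 5, axisLen = 9)
  expect_lt(max(abs(colSums(dynamicSpectra(sp2)@dyn))), 1e-10)
  # mismatched explicit reference is rejected
  expect_error(dynamicSpectra(sp2, reference = c(1, 2)), "does not match")
})

test_that("the synchronous map equals its definition", {
  wn <- seq(4000, 10000, length.out = 2)
  sp <- NIRSpectra(cbind(c(1, 3), c(3, 1)), wn, sampleId = c("a", "b"),
                   classLabel = "x")
  phi <- phiMatrix(syncMap(dynamicSpectra(sp)))
  expect_equal(unname(phi), rbind(c(2, -2), c(-2, 2)))
  zero <- methods::new("DynamicSpectra", dyn = matrix(0, 3, 4),
                       wavenumber = 1:4, reference = rep(0, 4))
  expect_true(all(phiMatrix(syncMap(zero)) == 0))
})

test_that("the synchronous map matches a brute-force double loop", {
  set.seed(42)
  sp <- tinyCollection(n = 5, axisLen = 8, seed = 42)
  dyn <- dynamicSpectra(sp)
  phi <- phiMatrix(syncMap(dyn))
  expect_lt(max(abs(phi - bruteForceSyncMap(dyn@dyn))), 1e-12)
})

test_that("a single perturbation point is rejected with guidance", {
  one <- tinyCollection(n = 1, axisLen = 6)
  expect_error(syncMap(dynamicSpectra(one, reference = rep(0, 6))),
               "perSampleSyncMap")
})

test_that("per-sample maps are rank-1 outer products with non-negative diagonal", {
  expect_true(all(phiMatrix(perSampleSyncMap(c(1, 2, 3),
                                             c(1, 2, 3))) == 0))
  phi <- phiMatrix(perSampleSyncMap(c(0, 2), c(1, 1)))
  expect_equal(phi, rbind(c(1, -1), c(-1, 1)))
  set.seed(1)
  s <- runif(7); r <- runif(7)
  phi <- phiMatrix(perSampleSyncMap(s, r))
  expect_equal(diag(phi), (s - r)^2)
  expect_true(all(diag(phi) >= 0))
  expect_error(perSampleSyncMap(c(1, 2), c(1, 2, 3)), "lengths differ")
})

test_that("per-sample maps average to the collection map up to m/(m-1)", {
  sp <- tinyCollection(n = 6, axisLen = 10, seed = 3)
  m <- ncol(sp)
  ref <- rowMeans(absorbance(sp))
  acc <- 0
  for (i in seq_len(m))
    acc <- acc + phiMatrix(perSampleSyncMap(sp, reference = ref, sample = i))
  phi <- phiMatrix(syncMap(dynamicSpectra(sp)))
  expect_equal(phi, (acc / m) * m / (m - 1), tolerance = 1e-12)
})

test_that("the map is PSD and scales quadratically with the spectra", {
  sp <- tinyCollection(n = 5, axisLen = 8, seed = 11)
  phi <- phiMatrix(syncMap(dynamicSpectra(sp)))
  expect_gt(min(eigen(phi, symmetric = TRUE, only.values = TRUE)$values),
            -1e-10)
  spC <- NIRSpectra(3 * absorbance(sp), wavenumbers(sp), sampleIds(sp),
                    classLabels(sp))
  phiC <- phiMatrix(syncMap(dynamicSpectra(spC)))
  expect_equal(phiC, 9 * phi, tolerance = 1e-10)
})

test_that("rendering produces square, symmetric, reproducible images", {
  sp <- tinyCollection(n = 5, axisLen = 30, seed = 2)
  map <- syncMap(dynamicSpectra(sp))
  img <- renderMap(map, sizePx = 224)
  expect_equal(dim(img$pixels), c(224, 224, 3))
  # a symmetric map renders to a transpose-symmetric level grid
  expect_identical(img$levels, t(img$levels))
  f1 <- withr::local_tempfile(fileext = ".png")
  f2 <- withr::local_tempfile(fileext = ".png")
  renderMap(map, sizePx = 64, file = f1)
  renderMap(map, sizePx = 64, file = f2)
  expect_identical(unname(tools::md5sum(f1)), unname(tools::md5sum(f2)))
  expect_error(renderMap(map, sizePx = 8), ">= 16")
})

test_that("binning preserves the pointwise mean and metadata", {
  sp <- tinyCollection(n = 3, axisLen = 40, seed = 5)
  b <- binSpectra(sp, 8)
  expect_equal(nrow(b), 8)
  expect_equal(ncol(b), 3)
  expect_equal(mean(absorbance(b)[, 1]), mean(absorbance(sp)[, 1]),
               tolerance = 1e-12)
  expect_equal(sampleIds(b), sampleIds(sp))
})
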