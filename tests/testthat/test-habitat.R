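test_that("collinear variables are eliminated, keeping the higher priority", {
  set.seed(1)
  a <- rnorm(30)
  df <- data.frame(a = a, b = a, c = rnorm(30))
  res <- spearmanFilter(df)
  expect_equal(res$retained, c("a", "c"))  # duplicate: one of the pair kept
  expect_equal(res$dropped$dropped, "b")
  # a monotone transform has identical ranks: Spearman invariance
  df2 <- data.frame(x = a, y = exp(a), z = rnorm(30))
  expect_equal(spearmanFilter(df2)$retained, c("x", "z"))
  # explicit priority reverses the verdict
  res3 <- spearmanFilter(df, priority = c("b", "a"))
  expect_equal(res3$retained, c("b", "c"))
})

test_that("greedy elimination matches the brute-force pair scan", {
  set.seed(13)
  for (rep in 1:4) {
    base <- rnorm(25)
    df <- data.frame(v1 = base + rnorm(25, sd = 0.1),
                     v2 = -base + rnorm(25, sd = 0.1),
                     v3 = rnorm(25),
                     v4 = base^3 + rnorm(25, sd = 0.05))
    expect_equal(spearmanFilter(df)$retained,
                 bruteForceSpearmanFilter(df))
  }
})

test_that("constant columns are flagged and excluded from testing", {
  df <- data.frame(a = rnorm(10), k = rep(1, 10), b = rnorm(10))
  expect_warning(res <- spearmanFilter(df), "constant")
  expect_equal(res$flagged, "k")
  expect_true("k" %in% res$retained)
  expect_error(spearmanFilter(df[1:2, ]), "at least 3")
})

test_that("variable filtering is independent of observation order", {
  set.seed(2)
  base <- rnorm(40)
  df <- data.frame(p = base, q = base + rnorm(40, sd = 0.05), r = rnorm(40))
  perm <- sample(40)
  expect_equal(spearmanFilter(df)$retained, spearmanFilter(df[perm, ])$retained)
})

test_that("main factors are the minimal prefix reaching the cumulative cutoff", {
  expect_equal(selectMainFactors(c(a = 90, b = 10)), "a")
  expect_equal(selectMainFactors(c(a = 50, b = 30, c = 10, d = 10)),
               c("a", "b", "c"))  # cumulative 90 >= 85
  u <- setNames(rep(10, 10), letters[1:10])
  expect_length(selectMainFactors(u), 9)
  expect_error(selectMainFactors(numeric(0)), "no contributions")
  expect_error(selectMainFactors(c(a = -1, b = 5)), ">= 0")
})

test_that("suitability thresholding is inclusive at exactly 0.5", {
  r <- SuitabilityRaster(matrix(c(0.5, 0.499, NA, 1), 2, 2))
  m <- classifySuitability(r)
  expect_s4_class(m, "BinaryHabitatMap")
  expect_equal(gridValues(m)[1, 1], 1)  # 0.5 -> suitable
  expect_equal(gridValues(m)[2, 1], 0)  # 0.499 -> unsuitable
  expect_true(is.na(gridValues(m)[1, 2]))
  allNA <- SuitabilityRaster(matrix(NA_real_, 3, 3))
  expect_true(all(is.na(gridValues(classifySuitability(allNA)))))
})

test_that("raising a cell's index never flips suitable to unsuitable", {
  set.seed(4)
  g <- matrix(runif(25), 5, 5)
  before <- gridValues(classifySuitability(SuitabilityRaster(g)))
  g2 <- matrix(pmin(g + runif(25, 0, 0.3), 1), 5, 5)
  after <- gridValues(classifySuitability(SuitabilityRaster(g2)))
  expect_true(all(after >= before))
})

test_that("overlay is a logical AND of the limiting factors", {
  c1 <- BinaryHabitatMap(matrix(1, 2, 2))
  s1 <- BinaryHabitatMap(matrix(1, 2, 2))
  veg <- matrix(1, 2, 2)
  expect_true(all(gridValues(overlayHabitat(c1, s1, veg)) == 1))
  s0 <- BinaryHabitatMap(matrix(0, 2, 2))
  expect_true(all(gridValues(overlayHabitat(c1, s0, veg)) == 0))
  expect_error(overlayHabitat(c1, BinaryHabitatMap(matrix(1, 3, 3)), veg),
               "shapes differ")
})

test_that("overlay matches the cell-wise brute force on fixtures", {
  fx <- generateRasterFixture(12, 9, nRegions = 3, seed = 6)
  cm <- classifySuitability(fx$climate)
  sm <- classifySuitability(fx$soil)
  ov <- overlayHabitat(cm, sm, fx$vegetation, c(1, 2, 3))
  oracle <- bruteForceOverlay(gridValues(cm), gridValues(sm),
                              fx$vegetation, c(1, 2, 3))
  expect_equal(gridValues(ov), oracle)
  # commutative in the two binary layers
  ov2 <- overlayHabitat(sm, cm, fx$vegetation, c(1, 2, 3))
  expect_equal(gridValues(ov2), gridValues(ov))
  # idempotent under a permissive vegetation mask
  ov3 <- overlayHabitat(ov, ov, matrix(1, 12, 9), 1)
  expect_equal(gridValues(ov3), gridValues(ov))
})

test_that("area statistics count suitable cells per region", {
  g <- matrix(0, 5, 5); g[1:2, 1:5] <- 1
  m <- BinaryHabitatMap(g)
  reg <- matrix("A", 5, 5)
  at <- areaStats(m, reg, cellAreaKm2 = 1)
  expect_equal(at$area[at$region == "A"], 10 / 1e4)  # 10 km^2 in 10^4 km^2
  expect_equal(at$area[at$region == "Total"], 10 / 1e4)
  # empty suitable set
  at0 <- areaStats(BinaryHabitatMap(matrix(0, 3, 3)), matrix("A", 3, 3))
  expect_equal(at0$area, 0)
  # two regions conserve the total
  reg2 <- matrix(rep(c("A", "B"), c(10, 15)), 5, 5)
  at2 <- areaStats(m, reg2)
  expect_equal(sum(at2$area[at2$region != "Total"]),
               at2$area[at2$region == "Total"])
  # suitable cells without a region are tallied with a warning
  regNA <- reg; regNA[1, 1] <- NA
  expect_warning(at3 <- areaStats(m, regNA), "unassigned")
  expect_true("unassigned" %in% at3$region)
})

test_that("area shares reproduce simple ratios", {
  at <- areaTable(c(A = 2, B = 2))
  expect_equal(shareOfTotal(at, "A"), 50)
  expect_equal(shareOfTotal(at, c("A", "B")), 100)
  expect_equal(shareOfTotal(at, "A", "A"), 100)
  expect_error(shareOfTotal(at, "Z"), "not in table")
  expect_error(shareOfTotal(areaTable(c(A = 0), total = 0), "A"), "zero")
})

test_that("half-up rounding reports percentages the conventional way", {
  expect_equal(roundHalfUp(c(48.5, 49.4, 76.5)), c(49, 49, 77))
  expect_equal(roundHalfUp(2.345, 2), 2.35)
})

test_that("ESRI ASCII grids round-trip through write and read", {
  fx <- generateRasterFixture(7, 5, nRegions = 2, seed = 8)
  f <- withr::local_tempfile(fileext = ".asc")
  writeAsciiGrid(fx$climate, f)
  back <- readAsciiGrid(f, as = "suitability")
  expect_s4_class(back, "SuitabilityRaster")
  expect_equal(gridValues(back), gridValues(fx$climate), tolerance = 1e-12)
  expect_equal(gridHeaderOf(back), gridHeaderOf(fx$climate))
  # header is parsed case-insensitively and malformed files are rejected
  writeLines(c("ncols 2", "nrows 1", "xllcorner 0", "yllcorner 0",
               "cellsize 1"), f)
  expect_error(readAsciiGrid(f), "nodata_value")
})
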