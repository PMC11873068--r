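test_that("empty and deterministic field generation", {
  cfg0 <- synthFieldConfig(nCells = 0, seed = 3)
  f0 <- makeField(cfg0)
  expect_equal(nrow(groundTruth(f0)$cells), 0)
  expect_equal(nrow(groundTruth(f0)$puncta), 0)
  expect_true(all(dim(f0$stain) > 0))

  cfg <- synthFieldConfig(nCells = 50, seed = 7)
  f1 <- makeField(cfg)
  f2 <- makeField(cfg)
  expect_identical(f1@channels, f2@channels)
  expect_identical(groundTruth(f1)$puncta, groundTruth(f2)$puncta)
})

test_that("config validation rejects malformed proportions and sizes", {
  expect_error(synthFieldConfig(ploidyWeights = c("2" = 0.5, "4" = 0.4)),
               "sum to 1")
  expect_error(synthFieldConfig(punctaCopyWeights = rep(0.2, 4)), "sum to 1")
  expect_error(synthFieldConfig(quantalIntensity = -5), "positive")
  expect_error(synthFieldConfig(transfectedFraction = 1.5), "proportion")
  # overcrowding: explicit failure, not silent overlap
  expect_error(makeField(synthFieldConfig(nCells = 500,
                                          fieldSizePx = c(300, 300),
                                          seed = 1)),
               "overcrowded")
})

test_that("ground-truth copies are conserved and intensities quantal", {
  cfg <- synthFieldConfig(nCells = 120, copiesPerCellMean = 400,
                          quantalIntensity = 100, seed = 5)
  f <- makeField(cfg)
  gt <- groundTruth(f)
  sums <- tapply(gt$puncta$copies, gt$puncta$cell, sum)
  withP <- gt$cells$copies[gt$cells$cell %in% as.integer(names(sums))]
  expect_identical(as.integer(sums), as.integer(withP))
  # mean ground-truth intensity per cell recovers copies * q within 2%
  isum <- tapply(gt$puncta$intensity, gt$puncta$cell, sum)
  expect_lt(abs(mean(isum) / 100 - mean(gt$cells$copies)) /
              mean(gt$cells$copies), 0.02)
  # puncta never inside nuclei
  d2 <- (gt$puncta$x - gt$cells$x[gt$puncta$cell])^2 +
        (gt$puncta$y - gt$cells$y[gt$puncta$cell])^2
  expect_true(all(sqrt(d2) > gt$cells$radiusPx[gt$puncta$cell]))
  # centroids within field bounds
  expect_true(all(gt$puncta$x >= 0 & gt$puncta$x < ncol(f$stain)))
  expect_true(all(gt$puncta$y >= 0 & gt$puncta$y < nrow(f$stain)))
})

test_that("droplet generator obeys Poisson statistics", {
  d0 <- makeDroplets(0, 0, 500, seed = 1)
  expect_true(all(d0$occNd1 == 0) && all(d0$occActb == 0))

  d <- makeDroplets(1.0, 0, 100000, seed = 2)
  negFrac <- mean(d$occNd1 == 0)
  expect_lt(abs(negFrac - exp(-1)), 0.005)

  d2 <- makeDroplets(1.9467, 0.020, 20000, seed = 3)
  dp <- mean(d2$occNd1 > 0 & d2$occActb > 0)
  expTrue <- (1 - exp(-1.9467)) * (1 - exp(-0.020))
  expect_lt(abs(dp - expTrue), 3 * sqrt(expTrue * (1 - expTrue) / 20000) + 1e-9)

  expect_identical(makeDroplets(1.5, 0.1, 1000, seed = 9),
                   makeDroplets(1.5, 0.1, 1000, seed = 9))
  # negative fractions match exp(-lambda) within 3 binomial SDs
  for (lam in c(0.05, 0.5, 2)) {
    dd <- makeDroplets(lam, 0.3, 20000, seed = 11)
    p <- exp(-lam)
    expect_lt(abs(mean(dd$occNd1 == 0) - p), 3 * sqrt(p * (1 - p) / 20000))
  }
})

test_that("growth-count generator matches the closed form", {
  g <- makeGrowthCounts(100, 0, 0, 24, 1, "none")
  expect_true(all(g$count == 100))

  g2 <- makeGrowthCounts(100, 0.06931, 0, 72, 1, "none")
  expect_equal(tail(g2$count, 1), 100 * exp(0.06931 * 72), tolerance = 1e-9)
  expect_equal(tail(g2$count, 1), 14700, tolerance = 0.01)

  expect_identical(makeGrowthCounts(100, 0.03, 0, 48, 1/3, "poisson", seed = 4),
                   makeGrowthCounts(100, 0.03, 0, 48, 1/3, "poisson", seed = 4))
  gt <- makeGrowthCounts(100, 0.2, 0, 72, 1, "none", maxCount = 5000)
  expect_true(attr(gt, "truncated"))
  expect_true(all(gt$count <= 5000))
})

test_that("OCR trace generator reproduces phase structure", {
  tr <- makeOcrTrace(c(100, 40, 150, 10), nPerPhase = 3, noiseSd = 0)
  expect_equal(as.numeric(tapply(tr$ocr, tr$phase, mean)),
               c(100, 40, 150, 10))
  expect_identical(makeOcrTrace(c(1, 2, 3, 4), 3, 5, seed = 8),
                   makeOcrTrace(c(1, 2, 3, 4), 3, 5, seed = 8))
  # phase means recovered within 3 * noise / sqrt(n)
  tr2 <- makeOcrTrace(c(100, 40, 150, 10), nPerPhase = 12, noiseSd = 5,
                      seed = 21)
  mns <- tapply(tr2$ocr, tr2$phase, mean)
  expect_true(all(abs(mns - c(100, 40, 150, 10)) < 3 * 5 / sqrt(12)))
  expect_error(makeOcrTrace(c(1, 2, 3), 3), "length")
})

test_that("pooled synthetic GFP levels are recovered by the mixture fit", {
  cfg <- synthFieldConfig(nCells = 6000, pixelSizeUm = 1.24,
                          cellSpacingUm = 40, punctaOuterUm = 15,
                          copiesPerCellMean = 0, channels = "stain",
                          seed = 13)
  f <- makeField(cfg)
  gt <- groundTruth(f)$cells
  fit <- fitGfpMixture(gt$gfpLevel, seed = 1)
  expect_lt(abs(fit@mu[1] - 100) / 100, 0.05)
})
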