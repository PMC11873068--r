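test_that("sub-threshold masking excludes pixels from downstream statistics", {
  img <- matrix(c(rep(10, 50), rep(100, 50)), 10, 10)
  expect_identical(maskSubthreshold(img, 0), img)
  m <- maskSubthreshold(img, 50)
  expect_equal(mean(m, na.rm = TRUE), 100)
  expect_true(all(is.na(m[img < 50])))
  # thresholded area: count of non-ignored pixels x pixel area
  lab <- matrix(1L, 10, 10)
  a <- thresholdedAreaPerCell(img, lab, 50, pixelSizeUm = 1.24)
  expect_equal(a$areaUm2, 50 * 1.24^2)
})

test_that("puncta detection finds isolated spots and assigns owners", {
  blank <- matrix(0, 50, 50)
  cyto <- matrix(1L, 50, 50)
  expect_equal(nrow(detectPuncta(blank, cyto, 1)), 0)

  img <- matrix(0, 80, 80)
  xs <- c(15, 40, 65, 20, 60); ys <- c(15, 20, 30, 60, 65)
  img <- .renderSpots(img, xs, ys, rep(500, 5), 1.5)
  pk <- detectPuncta(img, cyto = matrix(3L, 80, 80), peakMin = 2,
                     smoothSigma = 0, localBgRing = 0)
  expect_equal(nrow(pk), 5)
  expect_true(all(pk$cell == 3L))
  ord <- order(pk$x)
  expect_equal(pk$x[ord], sort(xs), tolerance = 0)
  # integrated intensity close to the rendered total (5x5 patch, sigma 1.5)
  expect_equal(mean(pk$intensity), 500 * 0.817, tolerance = 0.02)
})

test_that("plateau maxima resolve to the lexicographically first pixel", {
  img <- matrix(0, 20, 20)
  img[10:11, 10:11] <- 5     # 2x2 plateau
  pk <- detectPuncta(img, matrix(1L, 20, 20), peakMin = 1, smoothSigma = 0)
  expect_equal(nrow(pk), 1)
  expect_equal(c(pk$y, pk$x), c(9, 9))   # 0-based (row, col) first
})

test_that("detection count is non-increasing in peakMin", {
  set.seed(4)
  img <- matrix(rnorm(200 * 200, 0, 1), 200, 200)
  img <- .renderSpots(img, runif(60, 10, 190), runif(60, 10, 190),
                      runif(60, 80, 400), 1.5)
  cyto <- matrix(1L, 200, 200)
  counts <- vapply(c(2, 4, 6, 10, 20),
                   function(pm) nrow(detectPuncta(img, cyto, pm)),
                   numeric(1))
  expect_true(all(diff(counts) <= 0))
})

test_that("per-cell sums conserve punctum intensity exactly", {
  p <- data.frame(cell = c(3L, 3L, 1L, 0L), intensity = c(100, 200, 50, 999))
  s <- sumPunctaPerCell(p, cellIds = 1:4)
  expect_equal(s$punctaSum, c(50, 0, 300, 0))
  expect_equal(sum(s$punctaSum), sum(p$intensity[p$cell > 0]))
  expect_equal(sumPunctaPerCell(p[0, ], cellIds = 1:3)$punctaSum, rep(0, 3))
})

test_that("detection and per-cell sums recover ground truth in a resolvable field", {
  cfg <- synthFieldConfig(nCells = 25, pixelSizeUm = 0.5, psfSigmaPx = 1.0,
                          cellSpacingUm = 130, punctaOuterUm = 55,
                          copiesPerCellMean = 60, quantalIntensity = 100,
                          punctaSigma = 8, seed = 17)
  f <- makeField(cfg)
  gt <- groundTruth(f)
  dsd <- subtractBackground(f$dsdna, 75, 0.5)
  st <- subtractBackground(f$stain, 75, 0.5)
  lab <- thresholdNuclei(st, 6, pixelSizeUm = 0.5)
  roi <- voronoiCellRois(lab, 4, 133, 0.5)
  pk <- detectPuncta(dsd, roi@cytosol, peakMin = 6)
  # detected count per field >= 95% of ground truth at this SNR (~11)
  expect_gt(nrow(pk), 0.95 * nrow(gt$puncta))
  # per-cell sums: conservation within the detected table is exact
  s <- sumPunctaPerCell(pk, cellIds = seq_len(max(lab)))
  expect_equal(sum(s$punctaSum), sum(pk$intensity[pk$cell > 0]))
  # and within 5% of ground-truth total intensity per cell on average
  gts <- tapply(gt$puncta$intensity, gt$puncta$cell, sum)
  tab <- roiTable(lab, 0.5)
  idx <- vapply(seq_len(nrow(tab)), function(i)
    which.min((gt$cells$x - tab$x[i])^2 + (gt$cells$y - tab$y[i])^2),
    integer(1))
  ratio <- s$punctaSum / as.numeric(gts[as.character(idx)])
  expect_lt(abs(mean(ratio, na.rm = TRUE) - 1), 0.05)
})
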