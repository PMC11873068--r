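test_that("background subtraction removes flat background, keeps small disks", {
  u <- matrix(7, 60, 60)
  expect_true(all(subtractBackground(u, 10, 1) == 0))

  # a bright disk smaller than the rolling radius is preserved within 1%
  img <- matrix(10, 120, 120)
  img <- .renderDisks(img, 60, 60, 8, 50)
  out <- subtractBackground(img, 30, 1, presmoothSigma = 0)
  oracle <- img - bruteOpening(img, 30)
  expect_equal(out, oracle, tolerance = 1e-9)
  expect_lt(abs(sum(out) - sum(img - 10)) / sum(img - 10), 0.01)
  expect_true(all(out >= 0))

  expect_error(subtractBackground(u, 1, 1), "degenerate")
  # default radius convention: 1.5 x ~50 um nuclear diameter = 75 um
  expect_equal(formals(subtractBackground)$radiusUm, 75)
})

test_that("shrink-accelerated background stays close to the exact opening", {
  set.seed(5)
  img <- matrix(rnorm(300 * 300, 20, 1.4), 300, 300)
  img <- .renderSpots(img, runif(50, 20, 280), runif(50, 20, 280),
                      rep(300, 50), 1.5)
  fast <- subtractBackground(img, 150, 1, shrinkAbovePx = 100)
  exact <- subtractBackground(img, 150, 1, shrinkAbovePx = Inf)
  # same spot signal recovered by both paths
  expect_lt(abs(sum(fast) - sum(exact)) / sum(exact), 0.05)
})

test_that("nuclear thresholding labels 8-connected supra-threshold disks", {
  blank <- matrix(0.5, 80, 80)
  expect_warning(lab0 <- thresholdNuclei(blank, 1, 0, Inf, 1), "no nuclei")
  expect_equal(max(lab0), 0)

  img <- matrix(0, 100, 100)
  img <- .renderDisks(img, c(25, 70), c(30, 60), c(6, 6), c(10, 10))
  lab <- thresholdNuclei(img, 5, minAreaUm2 = 10, pixelSizeUm = 1)
  expect_equal(max(lab), 2)
  tab <- roiTable(lab, 1)
  expect_equal(tab$x, c(25, 70), tolerance = 0.1)
  expect_equal(tab$y, c(30, 60), tolerance = 0.1)

  # label count invariant under joint rescaling of image and threshold
  lab2 <- thresholdNuclei(img * 37, 5 * 37, minAreaUm2 = 10, pixelSizeUm = 1)
  expect_equal(lab, lab2, ignore_attr = TRUE)
  expect_equal(attr(lab, "provenance")$connectivity, 8L)
})

test_that("segmentation recovers synthetic nuclei and centroids", {
  cfg <- synthFieldConfig(nCells = 100, pixelSizeUm = 1.24,
                          cellSpacingUm = 60, punctaOuterUm = 20,
                          copiesPerCellMean = 0, channels = "stain",
                          seed = 31)
  f <- makeField(cfg)
  st <- subtractBackground(f$stain, 75, 1.24)
  lab <- thresholdNuclei(st, 30, pixelSizeUm = 1.24)
  expect_equal(max(lab), 100)
  tab <- roiTable(lab, 1.24)
  gt <- groundTruth(f)$cells
  idx <- vapply(seq_len(nrow(tab)), function(i)
    which.min((gt$x - tab$x[i])^2 + (gt$y - tab$y[i])^2), integer(1))
  expect_true(all(sqrt((tab$x - gt$x[idx])^2 + (tab$y - gt$y[idx])^2) < 2))
})

test_that("Voronoi expansion matches the brute-force oracle", {
  # two point-like nuclei: boundary at the perpendicular bisector
  lab <- matrix(0L, 60, 160)
  lab[30, 31] <- 1L; lab[30, 131] <- 2L
  roi <- voronoiCellRois(lab, dilationPx = 0, maxExpansionUm = 1e4,
                         pixelSizeUm = 1)
  expect_equal(roi@cells[30, 31 + 40], 1L)  # 40 px from nucleus 1, 60 from 2
  expect_equal(roi@cells[30, 131 - 40], 2L)

  # random many-nucleus fields against the O(px x nuclei) oracle
  for (seed in 1:3) {
    set.seed(seed)
    n <- 12
    cen <- cbind(sample(8:93, n), sample(8:93, n))
    labr <- diskLabels(c(100, 100), cen, 4)
    labr <- .label8(labr > 0)      # relabel contiguously, raster order
    capUm <- c(15, 30, 1e4)[1 + (seed %% 3)]
    roi <- voronoiCellRois(labr, dilationPx = 2, maxExpansionUm = capUm,
                           pixelSizeUm = 1)
    oracle <- bruteVoronoi(labr, floor(capUm))
    expect_identical(roi@cells, oracle$label)
    # cytosol = cell minus dilated nucleus, disjoint from nuclei
    expect_true(all(roi@cytosol[labr > 0] == 0))
    expect_true(all((roi@cytosol == roi@cells)[oracle$dist > 2.0001]))
  }
})

test_that("single nucleus expands to a disc of floor(cap/pixel) radius", {
  lab <- matrix(0L, 301, 301)
  lab[151, 151] <- 1L
  roi <- voronoiCellRois(lab, dilationPx = 4, maxExpansionUm = 133,
                         pixelSizeUm = 1.24)
  capPx <- floor(133 / 1.24)
  expect_equal(capPx, 107)
  d <- sqrt(outer((1:301 - 151)^2, (1:301 - 151)^2, "+"))
  expect_identical(roi@cells == 1L, d <= capPx)
})

test_that("shrinking the expansion cap never grows a cell ROI", {
  set.seed(9)
  cen <- cbind(sample(10:90, 8), sample(10:90, 8))
  lab <- .label8(diskLabels(c(100, 100), cen, 4) > 0)
  areas <- sapply(c(40, 25, 12, 6), function(capUm) {
    roi <- voronoiCellRois(lab, 2, capUm, pixelSizeUm = 1)
    tabulate(roi@cells[roi@cells > 0], max(lab))
  })
  expect_true(all(diff(t(areas)) <= 0))
})
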