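test_that("quadrant classification is accurate, idempotent, and flags degeneracy", {
  d <- makeDroplets(1.0, 0.3, 5000, seed = 3)
  cl <- classifyDroplets(d)
  truth <- ifelse(d$occNd1 > 0 & d$occActb > 0, "double",
                  ifelse(d$occNd1 > 0, "nd1",
                         ifelse(d$occActb > 0, "actb", "negative")))
  expect_gt(mean(as.character(cl$class) == truth), 0.995)
  # idempotent under the same thresholds
  thr <- attr(cl, "thresholds")
  cl2 <- classifyDroplets(cl, gates = thr)
  expect_identical(cl$class, cl2$class)
  # background-only: everything negative under manual gates
  d0 <- makeDroplets(0, 0, 2000, seed = 5)
  cl0 <- classifyDroplets(d0, gates = c(3000, 3000))
  expect_true(all(cl0$class == "negative"))
  # auto gating on a unimodal channel is flagged
  cl0a <- classifyDroplets(d0, gates = "auto")
  expect_true(any(attr(cl0a, "separationFlag")))
})

test_that("Poisson correction inverts the void probability", {
  expect_equal(poissonConcentration(100, 100), 0, ignore_attr = TRUE)
  expect_equal(poissonConcentration(3679, 10000), 1.0, tolerance = 1e-4,
               ignore_attr = TRUE)
  expect_equal(poissonConcentration(1427, 10000), -log(0.1427),
               ignore_attr = TRUE)
  expect_equal(poissonConcentration(1427, 10000), 1.9467, tolerance = 1e-3,
               ignore_attr = TRUE)
  expect_warning(lamSat <- poissonConcentration(0, 1000), "lower bound")
  expect_true(attr(lamSat, "saturated"))
  expect_error(poissonConcentration(-1, 10))
})

test_that("copies per cell scales with the nuclear reference loci", {
  expect_equal(copiesPerCell(1, 1, 1), 1)
  expect_equal(copiesPerCell(1.9467, 0.020, 6), 584.01)
  expect_equal(copiesPerCell(2 * 1.9467, 0.020, 6),
               2 * copiesPerCell(1.9467, 0.020, 6))
  expect_error(copiesPerCell(1, 0, 6), "positive")
})

test_that("round trip: generate, classify, Poisson-correct within 3 SEs", {
  for (lam in c(0.01, 0.1, 1, 3)) {
    est <- estimateConcentration(makeDroplets(lam, 0.5, 20000, seed = 31))
    p <- exp(-lam)
    seLam <- sqrt((1 - p) / (20000 * p))
    expect_lt(abs(est@lambdaNd1 - lam), 3 * seLam + 1e-9,
              label = sprintf("lambda %g", lam))
  }
})

test_that("copies per cell is invariant to droplet count (volume cancels)", {
  e1 <- estimateConcentration(makeDroplets(1.5, 0.1, 8000, seed = 12))
  e2 <- estimateConcentration(makeDroplets(1.5, 0.1, 40000, seed = 13))
  rel <- abs(copiesPerCellOf(e1) - copiesPerCellOf(e2)) / copiesPerCellOf(e2)
  # both estimate the same ratio; differences are sampling noise only
  expect_lt(rel, 0.15)
  expect_equal(e1@lociPerCell, 6)
})

test_that("QX200-style droplet CSVs are accepted", {
  tf <- tempfile(fileext = ".csv")
  write.csv(data.frame(`Ch1 Amplitude` = c(1000, 5000),
                       `Ch2 Amplitude` = c(900, 5100),
                       check.names = FALSE), tf, row.names = FALSE)
  d <- readDropletCsv(tf)
  expect_named(d, c("ch1", "ch2"))
  unlink(tf)
})
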