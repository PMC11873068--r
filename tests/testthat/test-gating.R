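gfpComp <- rbind(c(100, 20, 0.75), c(500, 80, 0.15), c(2000, 300, 0.10))

test_that("triple-Gaussian fit recovers components and the mu1+3sd1 gate", {
  x <- drawGfp(10000, gfpComp, seed = 42)
  f <- fitGfpMixture(x, seed = 1)
  expect_true(f@valid)
  expect_equal(f@mu, c(100, 500, 2000), tolerance = 0.06)
  expect_equal(f@threshold, f@mu[1] + 3 * f@sigma[1])
  # configured transfected mass 25%, recovered within 2 percentage points
  expect_lt(abs(f@fractionAbove - 0.25), 0.02)
  expect_error(fitGfpMixture(x[1:100]), "at least 1000")
})

test_that("transfection threshold is affine-consistent and beats one component", {
  x <- drawGfp(5000, gfpComp, seed = 7)
  f0 <- fitGfpMixture(x, seed = 3)
  f1 <- fitGfpMixture(x + 500, seed = 3)
  expect_equal(f1@threshold - 500, f0@threshold, tolerance = 0.02 * f0@threshold)
  # nesting sanity: 3-component loglik >= best single Gaussian
  ll1 <- sum(dnorm(x, mean(x), sd(x), log = TRUE))
  expect_gte(f0@logLik, ll1)
})

test_that("a pure background population yields the 3-sigma tail fraction", {
  set.seed(11)
  x <- rnorm(20000, 100, 20)
  f <- gaussianMixtureEM <- quantalCN:::gaussianMixtureEM
  fit <- f(x, G = 3, seed = 5)
  thr <- fit$mu[1] + 3 * fit$sigma[1]
  # fraction above mu1+3sd1 is near the normal tail mass 0.00135 when the
  # fitted components all describe the same background
  expect_lt(mean(x > thr), 0.02)
})

test_that("ploidy gates classify by intensity boxes derived from the G1 peak", {
  set.seed(21)
  n <- 3000
  cls <- sample(c("2", "4", "8"), n, TRUE, prob = c(0.6, 0.3, 0.1))
  g <- c("2" = 2, "4" = 4, "8" = 8)[cls]
  cells <- data.frame(intensity = g * 5000 * (1 + 0.08 * rnorm(n)),
                      area = g * 100 * (1 + 0.1 * rnorm(n)))
  gates <- autoGatesFromG1Peak(cells)
  expect_lt(abs(gates@g1Mode - 10000) / 10000, 0.05)
  out <- gatePloidy(cells, gates)
  expect_gt(mean(out$ploidyClass == cls), 0.95)
  # fractions over all classes sum to one
  fr <- table(factor(out$ploidyClass,
                     c("2", "2S", "4", "4S", "8", "ungated"))) / n
  expect_equal(sum(fr), 1)
  # modal intensity at 2x and 4x the G1 peak gates as 4 and 8
  probe <- data.frame(intensity = gates@g1Mode * c(1, 2, 4),
                      area = rep(100, 3))
  expect_equal(gatePloidy(probe, gates)$ploidyClass, c("2", "4", "8"))
  # gate boundaries scale with a global intensity rescale
  cells2 <- cells; cells2$intensity <- cells2$intensity * 3
  gates2 <- autoGatesFromG1Peak(cells2)
  expect_equal(gates2@gates$intMin / gates@gates$intMin, rep(3, 5),
               tolerance = 0.02)
})

test_that("pure-diploid populations gate entirely as 2N", {
  set.seed(8)
  cells <- data.frame(intensity = 10000 * (1 + 0.05 * rnorm(800)),
                      area = 100 * (1 + 0.05 * rnorm(800)))
  out <- gatePloidy(cells, autoGatesFromG1Peak(cells))
  expect_gt(mean(out$ploidyClass == "2"), 0.98)
})

test_that("fractionHigh counts strict exceedances", {
  expect_equal(fractionHigh(c(0, 0, 5, 10), 1), 0.5)
  expect_equal(fractionHigh(c(1, 2, 3), 10), 0)
  expect_error(fractionHigh(numeric(0), 1), "no finite")
  set.seed(3)
  v <- c(rnorm(700, 10, 2), rnorm(300, 50, 5))   # 30% high mass
  fl <- quantile(rnorm(100000, 10, 2), 0.95)
  frac <- fractionHigh(v, fl)
  expect_lt(abs(frac - (0.3 + 0.7 * 0.05)), 3 * sqrt(0.3 * 0.7 / 1000) + 0.01)
})

test_that("EM solution is at least as good as mclust's on the skewed mixture", {
  library(mclust)
  x <- drawGfp(8000, gfpComp, seed = 19)
  ours <- fitGfpMixture(x, seed = 2)
  ref <- Mclust(x, G = 3, modelNames = "V", verbose = FALSE)
  expect_gte(ours@logLik, ref$loglik - 1e-6 * abs(ref$loglik))
})
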