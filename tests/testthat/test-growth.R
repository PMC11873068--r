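test_that("noiseless exponentials are recovered exactly", {
  g <- makeGrowthCounts(100, 0.06931, 0, 24, 1, "none")
  f <- fitGrowth(g)
  expect_equal(f@k, 0.06931, tolerance = 1e-6)
  expect_equal(doublingTimeOf(f), 10.0, tolerance = 1e-4)
  expect_true(f@converged)

  # offset model recovers (a, k, c) exactly; the pure model is biased
  gc <- makeGrowthCounts(100, 0.06931, 50, 24, 1, "none")
  fo <- fitGrowth(gc, "offset_exponential")
  expect_equal(c(fo@a, fo@k, fo@c), c(100, 0.06931, 50), tolerance = 1e-5)
  fp <- fitGrowth(gc, "pure_exponential")
  expect_gt(abs(fp@k - 0.06931) / 0.06931, 0.01)
})

test_that("doubling-time arithmetic and sign handling", {
  expect_equal(doublingTime(0.6931), 1.0, tolerance = 1e-4)
  expect_equal(doublingTime(0.03381), 20.5, tolerance = 1e-3)
  expect_equal(doublingTime(0.01), 2 * doublingTime(0.02))
  expect_warning(td <- doublingTime(-0.1), "undefined")
  expect_true(is.na(td))
})

test_that("doubling times are recovered within 5% under Poisson noise", {
  # auto model selection: the offset is dropped when the window spans too
  # few doublings to identify it
  for (k in c(0.01, 0.025, 0.034, 0.06)) {
    errs <- vapply(1:10, function(s) {
      g <- makeGrowthCounts(150, k, 0, 72, 1/3, "poisson", seed = 100 + s)
      f <- fitGrowth(g, model = "auto")
      abs(doublingTimeOf(f) - log(2) / k) / (log(2) / k)
    }, numeric(1))
    expect_lt(median(errs), 0.05)
  }
})

test_that("rate is invariant to time-origin shifts", {
  g <- makeGrowthCounts(150, 0.03, 0, 48, 0.5, "poisson", seed = 5)
  g2 <- g; g2$time_h <- g2$time_h + 13
  f1 <- fitGrowth(g); f2 <- fitGrowth(g2)
  expect_equal(f1@k, f2@k, tolerance = 1e-6)
})

test_that("relative growth and rebasing", {
  g <- data.frame(time_h = 0:10, count = seq(100, 200, 10))
  expect_equal(relativeGrowth(g), 2.0)
  expect_equal(relativeGrowth(data.frame(time_h = 0:9, count = rep(7, 10))), 1)
  expect_equal(relativeGrowth(transform(g, count = count * 13)), 2.0)
  expect_error(relativeGrowth(data.frame(time_h = 0:8, count = c(0, 1:8))),
               "positive")

  r <- rebaseAtTime(g, 5)
  expect_equal(r$count[g$time_h == 5], 1)
  r0 <- rebaseAtTime(g, 0)
  expect_equal(r0$count, g$count / 100)
  # an exponential rebased anywhere keeps its rate
  ge <- makeGrowthCounts(100, 0.05, 0, 48, 1, "none")
  fr <- fitGrowth(rebaseAtTime(ge, 26), weighting = "none")
  expect_equal(fr@k, 0.05, tolerance = 1e-5)
  expect_error(rebaseAtTime(g, 99), "range")
})

test_that("degenerate series are rejected or flagged", {
  expect_error(fitGrowth(data.frame(time_h = 1:5, count = 1:5)), "8 time")
  expect_error(fitGrowth(data.frame(time_h = rep(1, 10), count = 1:10)),
               "increasing")
  expect_error(fitGrowth(data.frame(time_h = 1:10, count = rep(3, 10))),
               "all equal")
  # decaying counts: k < 0, doubling time undefined
  g <- data.frame(time_h = seq(0, 20, 2), count = 500 * exp(-0.05 * seq(0, 20, 2)))
  f <- fitGrowth(g, weighting = "none")
  expect_lt(f@k, 0)
  expect_true(is.na(doublingTimeOf(f)))
})
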