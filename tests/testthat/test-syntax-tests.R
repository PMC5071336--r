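test_that("signed-rank p-values match enumeration on the worked cases", {
  expect_equal(wsrPValue(c(0.1, 0.2, 0.3)), 0.25)
  expect_equal(wsrPValue(c(0.1, -0.1)), 1)
  expect_true(is.na(wsrPValue(c(0, 0, 0))))       # no informative pairs
  expect_true(is.na(wsrPValue(0.5)))              # a single pair
})

test_that("rank-sum p-values match enumeration on the worked cases", {
  expect_equal(wmwPValue(c(0.1, 0.2), c(0.3, 0.4)), 1 / 3)
  expect_equal(wmwPValue(c(1, 2, 3), c(1, 2, 3)), 1)
  ## heavy ties: {0,0,0} vs {1,1,1}, 2 of 20 assignments x 2 tails
  expect_equal(wmwPValue(c(0, 0, 0), c(1, 1, 1)), 0.1)
  expect_true(is.na(wmwPValue(1, c(2, 3))))
})

test_that("exact branches agree with stats::wilcox.test on tie-free data", {
  withr::with_seed(14, {
    for (rep in 1:25) {
      x <- rnorm(sample(2:6, 1)); y <- rnorm(sample(2:6, 1))
      expect_equal(wmwPValue(x, y),
                   wilcox.test(x, y, exact = TRUE)$p.value)
      d <- rnorm(sample(2:10, 1))
      expect_equal(wsrPValue(d), wilcox.test(d, exact = TRUE)$p.value)
    }
  })
})

test_that("approximate branches match wilcox.test with ties and correction", {
  withr::with_seed(15, {
    for (rep in 1:10) {
      x <- round(rnorm(8), 1); y <- round(rnorm(9), 1)
      expect_equal(wmwPValue(x, y, exactLimit = 2L),
                   suppressWarnings(
                     wilcox.test(x, y, exact = FALSE,
                                 correct = TRUE)$p.value))
      d <- round(rnorm(15), 1)
      d <- d[d != 0]
      expect_equal(wsrPValue(d, exactLimit = 2L),
                   suppressWarnings(
                     wilcox.test(d, exact = FALSE, correct = TRUE)$p.value))
    }
  })
})

test_that("the truncated product keeps only p-values at or below tau", {
  r <- tpmStatistic(c(0.5, 0.5), tau = 1)
  expect_equal(r$W, 0.25)
  expect_equal(r$k, 2L)
  expect_equal(fisherCombinedP(r$W, r$k), 0.25 * (1 - log(0.25)))
  expect_equal(tpmStatistic(c(0.2, 0.9), tau = 0.05)$W, 1)   # empty product
  expect_equal(tpmStatistic(c(0.03, 0.2, 0.9), tau = 0.05)$W, 0.03)
  expect_true(is.na(tpmStatistic(c(NA, NA), tau = 0.05)$W))
  expect_equal(fisherCombinedP(1, 0L), 1)
})

test_that("BH adjustment is step-up with cumulative minimum", {
  expect_equal(fdrAdjust(c(0.01, 0.02, 0.03, 0.04, 0.05)), rep(0.05, 5))
  expect_equal(fdrAdjust(0.37), 0.37)
  expect_equal(fdrAdjust(c(0.5, 1.0)), c(1, 1))
  expect_equal(fdrAdjust(c(0.02, NA, 0.5)), c(0.04, NA, 0.5))
})

test_that("local test matrices line up with per-cell scalar tests", {
  withr::with_seed(16, {
    g1 <- iidMatrices(5); g2 <- iidMatrices(6)
  })
  lp <- localTestsTwoSample(g1, g2)
  expect_true(is.na(lp["X", "X"]))
  expect_equal(sum(!is.na(lp)), 24L)
  expect_equal(lp["s", "d"],
               wmwPValue(vapply(g1, function(m) m["s", "d"], 1),
                         vapply(g2, function(m) m["s", "d"], 1)))
  lpp <- localTestsPaired(g1, g1[c(2:5, 1)])
  expect_equal(lpp["d", "m"],
               wsrPValue(vapply(g1, function(m) m["d", "m"], 1) -
                           vapply(g1[c(2:5, 1)], function(m) m["d", "m"], 1)))
  expect_error(localTestsPaired(g1, g2), "same animals")
})

test_that("the permutation test is deterministic and respects its bounds", {
  cohort <- sampleCohort(cohortSpec(nAnimals = 5, seqPerAnimal = 60),
                         seed = 17)
  g1 <- probsOf(cohort, "g1"); g2 <- probsOf(cohort, "g2")
  r1 <- syntaxTest(g1, g2, nPerm = 200, seed = 18)
  r2 <- syntaxTest(g1, g2, nPerm = 200, seed = 18)
  expect_identical(localP(r1), localP(r2))
  expect_identical(toP(r1), toP(r2))
  expect_identical(globalP(r1), globalP(r2))
  ## p-values live in [1/(B+1), 1]
  allP <- c(toP(r1), fromP(r1), globalP(r1))
  expect_true(all(allP >= 1 / 201 & allP <= 1))
  ## adjusted margins never drop below raw
  expect_true(all(toPAdjusted(r1) >= toP(r1), na.rm = TRUE))
  expect_true(all(fromPAdjusted(r1) >= fromP(r1), na.rm = TRUE))
  validObject(r1)
})

test_that("identical groups give p = 1 and too-small groups error", {
  withr::with_seed(19, g <- iidMatrices(4))
  r <- syntaxTest(g, g, nPerm = 100, seed = 20)
  expect_equal(globalP(r), 1)
  expect_error(syntaxTest(g[1], g, nPerm = 10), "at least 2")
  expect_error(syntaxTest(g[1:2], g[1:3], type = "paired"), "same animals")
})

test_that("cells with missing observed p-values are excluded throughout", {
  withr::with_seed(21, {
    g1 <- iidMatrices(4); g2 <- iidMatrices(4)
  })
  for (m in seq_along(g1)) g1[[m]]["u", ] <- NA    # no u-row data in group 1
  r <- syntaxTest(g1, g2, nPerm = 100, seed = 22)
  expect_true(all(is.na(localP(r)["u", ])))
  ## the from-u margin has no usable local tests but still reports a p of 1
  expect_equal(unname(fromP(r)["u"]), 1)
})

test_that("a paired comparison detects a within-animal context shift", {
  ## 8 animals; context B inflates transitions to silence by 0.2
  specA <- cohortSpec(nAnimals = 8, seqPerAnimal = 150,
                      toSilenceShift = c(g = 0), mFactor = c(g = 1))
  specB <- cohortSpec(nAnimals = 8, seqPerAnimal = 150,
                      toSilenceShift = c(g = 0.2), mFactor = c(g = 1))
  mA <- probsOf(sampleCohort(specA, seed = 23), "g")
  mB <- probsOf(sampleCohort(specB, seed = 24), "g")
  names(mB) <- names(mA)
  r <- syntaxTest(mA, mB, type = "paired", nPerm = 400, seed = 25)
  expect_lt(globalP(r), 0.05)
  expect_lt(toP(r)["X"], 0.05)
})
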