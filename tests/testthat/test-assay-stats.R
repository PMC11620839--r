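test_that("EOP equals the geometric mean of per-pair ratios", {
  same <- efficiencyOfPlating(c(1e8, 2e8, 3e8), c(1e8, 2e8, 3e8))
  expect_equal(same$eopPercent, 100)
  low <- efficiencyOfPlating(rep(1e3, 3), rep(1e8, 3))
  expect_equal(low$eopPercent, 0.001)
  for (s in 1:100) {
    test <- randomTiters(5, s)
    control <- randomTiters(5, s + 1000)
    eop <- efficiencyOfPlating(test, control)
    expect_equal(eop$eopPercent, oracleGeomMeanPercent(test / control),
      tolerance = 1e-12)
  }
  expect_error(efficiencyOfPlating(1:3 * 1.0, 1:2 * 1.0), "equal-length")
})

test_that("EOP is invariant to common rescaling of titers", {
  test <- randomTiters(4, 7); control <- randomTiters(4, 8)
  a <- efficiencyOfPlating(test, control)
  b <- efficiencyOfPlating(test * 10, control * 10)
  expect_equal(a$eopPercent, b$eopPercent)
  expect_equal(a$tStatistic, b$tStatistic)
  expect_equal(a$pValue, b$pValue)
})

test_that("fold-change divides by the control mean", {
  expect_equal(foldChange(c(2, 4, 6), c(2, 2, 2)), c(1, 2, 3))
  expect_equal(foldChange(c(5, 5), c(5, 5, 5)), c(1, 1))
  for (s in 1:50) {
    e <- randomTiters(6, s); ctl <- randomTiters(4, s + 500)
    expect_equal(foldChange(e, ctl), e / (sum(ctl) / length(ctl)),
      tolerance = 1e-12)
  }
  expect_error(foldChange(c(1, 2), numeric(0)), "non-empty")
  # control against itself has mean fold 1
  ctl <- randomTiters(5, 77)
  expect_equal(mean(foldChange(ctl, ctl)), 1)
})

test_that("ratio-paired t-test matches the closed form on log ratios", {
  unitRatios <- ratioPairedTTest(c(2, 3, 4), c(2, 3, 4))
  expect_equal(unitRatios$t, 0)
  expect_equal(unitRatios$p, 1)
  for (s in 1:50) {
    test <- randomTiters(5, s); control <- randomTiters(5, s + 250)
    got <- ratioPairedTTest(test, control)
    want <- oracleOneSampleT(log10(test / control))
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
  # ratio invariance: common rescaling changes nothing
  test <- randomTiters(4, 5); control <- randomTiters(4, 6)
  expect_equal(ratioPairedTTest(test, control),
    ratioPairedTTest(test * 10, control * 10))
  expect_error(ratioPairedTTest(1, 1), "at least two")
})

test_that("unpaired t-test matches the pooled-variance closed form", {
  same <- unpairedTTest(c(1, 1, 1), c(1, 1, 1))
  expect_equal(same$t, 0)
  expect_equal(same$p, 1)
  for (s in 1:50) {
    a <- randomTiters(5, s); b <- randomTiters(7, s + 750)
    got <- unpairedTTest(log10(a), log10(b))
    want <- oraclePooledT(log10(a), log10(b))
    expect_equal(got$t, want$t, tolerance = 1e-10)
    expect_equal(got$p, want$p, tolerance = 1e-10)
  }
  a <- rnorm(5); b <- rnorm(5, 1)
  expect_equal(unpairedTTest(a, b)$t, -unpairedTTest(b, a)$t)
  expect_equal(unpairedTTest(a, b)$p, unpairedTTest(b, a)$p)
  expect_error(unpairedTTest(1, c(1, 2)), "at least two")
})

test_that("capsid summaries reproduce the printed treated mean", {
  # 13 singly filled + 4 empty tomograms: mean 0.76 at two decimals
  counts <- c(rep(1L, 13), rep(0L, 4))
  s <- capsidCountSummary(counts)
  expect_equal(round(s$mean, 2), 0.76)
  expect_equal(s$n, 17L)
  expect_equal(capsidCountSummary(c(5, 5, 5))$sem, 0)
  expect_true(is.na(capsidCountSummary(3)$sem))
  for (seed in 1:20) {
    x <- withr::with_seed(seed, rpois(10, 20))
    got <- capsidCountSummary(x)
    want <- oracleMeanSem(x)
    expect_equal(got$mean, want$mean, tolerance = 1e-12)
    expect_equal(got$sem, want$sem, tolerance = 1e-12)
  }
})

test_that("percent decrease reproduces the virion-production figure", {
  expect_equal(percentDecrease(22.6, 0.76), 96.6)
  expect_equal(percentDecrease(5, 5), 0)
  expect_equal(percentDecrease(5, 0), 100)
  expect_error(percentDecrease(0, 1), "> 0")
})

test_that("import fractions reproduce the co-import split", {
  fr <- importFractions(c(co = 75, distinct = 65))
  expect_equal(unname(fr), c(53.6, 46.4))
  expect_lte(abs(sum(fr) - 100), 0.1)
  expect_equal(unname(importFractions(c(0, 10))), c(0, 100))
  expect_equal(unname(importFractions(c(10, 0))), c(100, 0))
  expect_error(importFractions(c(0, 0)), ">= 1")
})
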