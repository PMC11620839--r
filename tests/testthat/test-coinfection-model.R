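test_that("adsorption counts are Poisson with the requested MOI", {
  set.seed(1)
  expect_identical(sampleAdsorption(0, 100), integer(100))
  n <- 1e5
  set.seed(2)
  fr10 <- mean(sampleAdsorption(10, n) >= 1L)
  p10 <- 1 - exp(-10)
  expect_lt(abs(fr10 - p10), 3 * sqrt(p10 * (1 - p10) / n))
  set.seed(3)
  fr01 <- mean(sampleAdsorption(0.1, n) >= 1L)
  p01 <- 1 - exp(-0.1)
  expect_lt(abs(fr01 - p01), 3 * sqrt(p01 * (1 - p01) / n))
  expect_error(sampleAdsorption(-1, 10), "non-negative")
})

test_that("per-cell resolution follows the interference cascade", {
  strains <- defaultStrains(burstSize = 30, replicationRateB = 1)
  pKill <- interferenceParams(h = 1, k = 1, mu = 0, identity = 0)
  set.seed(4)
  expect_equal(resolveCell(0, 0, pKill, strains), c(A = 0, B = 0))
  # B alone, or facing an inactive endonuclease, always bursts
  inactive <- defaultStrains(burstSize = 30, replicationRateB = 1)
  inactive$A@endonucleaseActive <- FALSE
  expect_equal(resolveCell(0, 5, pKill, strains)[["B"]], 30)
  expect_equal(resolveCell(3, 1, pKill, inactive)[["B"]], 30)
  # forced kill and guaranteed exclusion
  expect_equal(resolveCell(3, 1, pKill, strains)[["B"]], 0)
  pNoHybrid <- interferenceParams(h = 0)
  expect_equal(resolveCell(3, 1, pNoHybrid, strains)[["B"]], 30)
  expect_equal(resolveCell(3, 1, pKill, strains)[["A"]], 30)
})

test_that("simulated fold-change matches the closed form", {
  p <- interferenceParams(moiA = 10, moiB = 0.1, h = 0.536, k = 1,
    mu = 0, identity = 0, nCells = 1e5, seed = 5)
  rr <- simulateRound(p)
  expect_lt(abs(foldChangeVsControl(rr) - 2.1550594),
    3 * foldChangeSE(rr))
  # without co-infection the advantage disappears
  pLow <- interferenceParams(moiA = 0.01, moiB = 0.01, h = 0.536, k = 1,
    mu = 0, identity = 0, nCells = 1e5, seed = 6)
  rrLow <- simulateRound(pLow)
  expect_lt(abs(foldChangeVsControl(rrLow) - expectedFoldChange(pLow)),
    3 * foldChangeSE(rrLow) + 1e-9)
  expect_lt(expectedFoldChange(pLow), 1.01)
})

test_that("inactive endonuclease gives fold-change exactly 1", {
  inactive <- defaultStrains()
  inactive$A@endonucleaseActive <- FALSE
  rr <- simulateRound(interferenceParams(nCells = 1e4, seed = 7), inactive)
  expect_equal(foldChangeVsControl(rr), 1)
})

test_that("carrier progeny is invariant to endonuclease status", {
  rr <- simulateRound(interferenceParams(nCells = 5e4, seed = 8))
  expect_identical(progenyPerStrain(rr)[["A"]], controlProgeny(rr)[["A"]])
})

test_that("rounds are reproducible bit-for-bit under a fixed seed", {
  p <- interferenceParams(nCells = 1e4, seed = 9)
  r1 <- simulateRound(p); r2 <- simulateRound(p)
  expect_identical(progenyPerStrain(r1), progenyPerStrain(r2))
  expect_identical(foldChangeVsControl(r1), foldChangeVsControl(r2))
})

test_that("expected fold-change has the right limits and values", {
  expect_equal(expectedFoldChange(interferenceParams(h = 0)), 1)
  expect_equal(
    expectedFoldChange(interferenceParams(moiA = 10, h = 1, k = 1,
      mu = 0, identity = 0)),
    exp(10))
  expect_equal(
    expectedFoldChange(interferenceParams(moiA = 10, h = 0.536, k = 1,
      mu = 0, identity = 0)),
    2.1550594, tolerance = 1e-7)
  # identity above threshold with full rescue disables interference
  expect_equal(expectedFoldChange(interferenceParams(identity = 1,
    rMax = 1, mu = 0)), 1)
})

test_that("interference fit inverts the closed form exactly", {
  p <- interferenceParams(moiA = 10)
  expect_equal(fitInterference(1, p)$q, 0)
  expect_equal(fitInterference(3.7, p)$q, 0.7297629, tolerance = 1e-6)
  for (f in c(1.5, 2, 3.7, 10)) {
    qHat <- fitInterference(f, p)$q
    back <- expectedFoldChange(interferenceParams(moiA = 10, h = qHat,
      k = 1, mu = 0, identity = 0))
    expect_lt(abs(back - f), 1e-9)
  }
  expect_error(fitInterference(0.5, p), "cannot increase")
  # implied k is clipped with a flag when q exceeds h (1 - mu)
  fit <- suppressWarnings(fitInterference(3.7,
    interferenceParams(moiA = 10, h = 0.536)))
  expect_true(fit$k <= 1 && fit$clipped)
})

test_that("fit recovers the interference strength of simulated data", {
  for (q in c(0.2, 0.5, 0.73)) {
    p <- interferenceParams(moiA = 10, moiB = 0.1, h = q, k = 1, mu = 0,
      identity = 0, nCells = 1e5, seed = 100 + round(100 * q))
    rr <- simulateRound(p)
    fit <- fitInterference(foldChangeVsControl(rr),
      interferenceParams(moiA = 10))
    f <- foldChangeVsControl(rr)
    # delta method: dq/dF = 1 / (F^2 (1 - P0))
    seQ <- foldChangeSE(rr) / (f^2 * (1 - exp(-10)))
    expect_lt(abs(fit$q - q), 3 * seQ)
  }
})

test_that("fold-change agrees with the closed form across a grid", {
  grid <- expand.grid(moiA = c(1, 3, 10), h = c(0.3, 0.536),
    k = c(0.7, 1))
  for (i in seq_len(nrow(grid))) {
    p <- interferenceParams(moiA = grid$moiA[i], moiB = 0.1,
      h = grid$h[i], k = grid$k[i], mu = 0, identity = 0,
      nCells = 1e5, seed = 1000 + i)
    rr <- simulateRound(p)
    expect_lt(abs(foldChangeVsControl(rr) - expectedFoldChange(p)),
      3 * foldChangeSE(rr))
  }
})

test_that("homing drives the intron allele to fixation when rescue is certain", {
  p <- interferenceParams(moiA = 1, moiB = 1, h = 1, k = 1, mu = 0,
    identity = 1, rMax = 1, compartmentalized = FALSE,
    nCells = 2e4, generations = 20L, seed = 10)
  tr <- simulateTrajectory(p)
  f <- intronFrequency(tr)
  expect_true(all(diff(f) >= -1e-12))
  expect_gt(f[length(f)], 0.99)
})

test_that("trajectory frequencies always sum to one", {
  tr <- simulateTrajectory(interferenceParams(moiA = 2, moiB = 2,
    nCells = 1e4, generations = 10L, seed = 11))
  tb <- trajectoryTable(tr)
  expect_true(all(abs(tb$freqA + tb$freqBplus + tb$freqBminus - 1) < 1e-9))
})

test_that("compartmentalized interference depresses the competitor", {
  p <- interferenceParams(moiA = 2, moiB = 2, h = 0.536, k = 1, mu = 0,
    compartmentalized = TRUE, nCells = 5e4, generations = 10L, seed = 12)
  deleted <- defaultStrains()
  deleted$A@endonucleaseActive <- FALSE
  trActive <- simulateTrajectory(p)
  trControl <- simulateTrajectory(p, strains = deleted)
  expect_true(all(trajectoryTable(trActive)$freqB <=
    trajectoryTable(trControl)$freqB + 1e-12))
})

test_that("h = 0 reproduces the endonuclease-deleted control exactly", {
  p <- interferenceParams(moiA = 2, moiB = 2, h = 0, nCells = 1e4,
    generations = 5L, seed = 13)
  deleted <- defaultStrains()
  deleted$A@endonucleaseActive <- FALSE
  expect_identical(trajectoryTable(simulateTrajectory(p)),
    trajectoryTable(simulateTrajectory(p, strains = deleted)))
})
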