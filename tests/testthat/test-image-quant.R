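test_that("uniform cells give ratio 1 and zero-flank cells ratio 0", {
  uniform <- cellImage(matrix(5, 40, 100))
  ru <- bouquetNucleusRatio(uniform)
  expect_true(ru$nucleusFound)
  expect_equal(ru$ratio, 1)
  # bright central block, exactly zero elsewhere
  m <- matrix(0, 40, 100)
  m[15:25, 40:60] <- 3
  rz <- bouquetNucleusRatio(cellImage(m))
  expect_true(rz$nucleusFound)
  expect_equal(rz$ratio, 0)
  # all-dark image: a distinct "no nucleus" outcome, not an error
  expect_false(bouquetNucleusRatio(cellImage(matrix(0, 10, 20)))$nucleusFound)
})

test_that("the ratio is invariant to global intensity rescaling", {
  set.seed(61)
  img <- genCellImage(4, 1, 0.8, noiseSd = 0.02)
  scaled <- cellImage(intensity(img) * 7, pixelSize(img),
    cellMask(img), longAxis(img))
  expect_equal(bouquetNucleusRatio(scaled)$ratio,
    bouquetNucleusRatio(img)$ratio, tolerance = 1e-12)
})

test_that("generated images are deterministic and peak at the nucleus", {
  img1 <- withr::with_seed(62, genCellImage(4, 1, 0.8, noiseSd = 0.02))
  img2 <- withr::with_seed(62, genCellImage(4, 1, 0.8, noiseSd = 0.02))
  expect_identical(intensity(img1), intensity(img2))
  nucleusOnly <- withr::with_seed(63, genCellImage(4, 1, 0, noiseSd = 0))
  m <- intensity(nucleusOnly)
  expect_equal(max(m), m[(nrow(m) + 1) / 2, (ncol(m) + 1) / 2])
  # equal nucleus and focus amplitudes: the global maximum stays at
  # the nucleus peak (foci are spaced, so they do not stack)
  both <- withr::with_seed(63, genCellImage(4, 1, 1, noiseSd = 0))
  expect_equal(max(intensity(both)), 1, tolerance = 0.02)
  expect_error(genCellImage(-1, 1, 1), "cellLength")
})

test_that("line profiles interpolate along the axis with a band average", {
  uniform <- cellImage(matrix(3, 40, 100))
  pr <- lineProfile(uniform)
  expect_true(all(abs(pr$intensity - 3) < 1e-12))
  expect_true(all(diff(pr$position) > 0))
  # noise-free cell: profile maximum at mid-cell within one pixel
  img <- withr::with_seed(64, genCellImage(4, 1, 0, noiseSd = 0))
  pr2 <- lineProfile(img)
  mid <- (max(pr2$position) + min(pr2$position)) / 2
  expect_lte(abs(pr2$position[which.max(pr2$intensity)] - mid),
    pixelSize(img))
  # linearity under a global multiplier
  img3 <- cellImage(intensity(img) * 2.5, pixelSize(img),
    cellMask(img), longAxis(img))
  expect_equal(sum(lineProfile(img3)$intensity),
    2.5 * sum(pr2$intensity), tolerance = 1e-9)
})

test_that("the two-cohort experiment reproduces the direction of effect", {
  ex <- bouquetRatioExperiment(n = 30, seed = 65)
  expect_gt(mean(ex$controlRatios), mean(ex$treatedRatios))
  expect_lt(ex$test$p, 0.001)
})
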