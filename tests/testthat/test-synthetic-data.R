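test_that("config validity rejects bad parameter values", {
  expect_error(syntheticConfig(pCoimport = 1.2), "pCoimport")
  expect_error(syntheticConfig(nReplicates = 0), "nReplicates")
  expect_error(syntheticConfig(genomeIdentity = -0.1), "genomeIdentity")
  badSpec <- data.frame(position = 1L, ref = "A", alt = "C", prob = 0.5)
  expect_error(syntheticConfig(escaperSiteProbs = badSpec), "sum to 1")
})

test_that("titer generator is exact at zero noise and deterministic", {
  cfg <- syntheticConfig(seed = 11, nReplicates = 3, titerLog10Sd = 0)
  tb <- genTiterTable(cfg, c(A = 1e9))
  expect_equal(nrow(tb), 3L)
  expect_equal(tb$titer_pfu_per_ml, rep(1e9, 3))
  cfg2 <- syntheticConfig(seed = 12, nReplicates = 4, titerLog10Sd = 0.3)
  expect_identical(genTiterTable(cfg2, c(A = 1e8, B = 2e7)),
    genTiterTable(cfg2, c(A = 1e8, B = 2e7)))
  expect_error(genTiterTable(cfg, c(A = -1)), "positive")
})

test_that("titer noise has the configured lognormal moments", {
  cfg <- syntheticConfig(seed = 13, nReplicates = 10000L, titerLog10Sd = 0.2)
  tb <- genTiterTable(cfg, c(A = 1e9))
  se <- 0.2 / sqrt(10000)
  expect_lt(abs(mean(log10(tb$titer_pfu_per_ml)) - 9), 3 * se)
  expect_lt(abs(sd(log10(tb$titer_pfu_per_ml)) - 0.2), 3 * se)
})

test_that("import counts follow the configured binomial", {
  expect_equal(genImportCounts(syntheticConfig(pCoimport = 1))[["co"]], 140L)
  expect_equal(genImportCounts(syntheticConfig(pCoimport = 0))[["co"]], 0L)
  draws <- vapply(seq_len(2000L), function(s)
    genImportCounts(syntheticConfig(seed = s))[["co"]], integer(1))
  se <- sqrt(140 * 0.536 * 0.464) / sqrt(2000)
  expect_lt(abs(mean(draws) - 75.04), 3 * se)
  expect_equal(sum(genImportCounts(syntheticConfig(seed = 5))), 140L)
})

test_that("capsid counts have negative-binomial moments and edge cases", {
  zero <- genCapsidCounts(syntheticConfig(capsidMeanTreated = 0), "treated")
  expect_identical(zero, integer(17))
  cfg <- syntheticConfig(seed = 21)
  big <- genCapsidCounts(cfg, "control", n = 5000L)
  sdTheory <- sqrt(22.6 + 22.6^2 / 16)
  expect_lt(abs(mean(big) - 22.6), 3 * sdTheory / sqrt(5000))
  expect_identical(genCapsidCounts(cfg, "treated"),
    genCapsidCounts(cfg, "treated"))
  expect_length(genCapsidCounts(cfg, "treated"), 17L)
  expect_error(genCapsidCounts(syntheticConfig(capsidMeanTreated = -1)),
    "means must be")
})

test_that("escaper spectrum is multinomial over the configured classes", {
  one <- data.frame(position = 3215L, ref = "A", alt = "C", prob = 1)
  all3215 <- genEscaperSpectrum(10, syntheticConfig(escaperSiteProbs = one))
  expect_true(all(all3215$position == 3215L & all3215$alt == "C"))
  expect_equal(nrow(genEscaperSpectrum(0, syntheticConfig())), 0L)

  spec <- data.frame(position = c(3215L, 3214L), ref = c("A", "G"),
    alt = c("C", "T"), prob = c(14 / 17, 3 / 17))
  big <- genEscaperSpectrum(17000L,
    syntheticConfig(seed = 31, escaperSiteProbs = spec))
  n3215 <- sum(big$position == 3215L)
  se <- sqrt(17000 * (14 / 17) * (3 / 17))
  expect_lt(abs(n3215 - 14000), 3 * se)
  expect_equal(nrow(big), 17000L)
})

test_that("toy genomes match the configured identity and structure", {
  ident <- genToyGenomes(syntheticConfig(genomeIdentity = 1, intronLength = 0))
  expect_equal(unname(ident$intronPlus), unname(ident$intronMinus))

  pair <- genToyGenomes(syntheticConfig(seed = 41, genomeIdentity = 0.6))
  plus <- unname(pair$exonPlus); minus <- unname(pair$intronMinus)
  pc <- strsplit(plus, "")[[1]]; mc <- strsplit(minus, "")[[1]]
  flanks <- c(seq_len(300), 313:612)
  flankId <- mean(pc[flanks] == mc[flanks])
  expect_gte(flankId, 0.58)
  expect_lte(flankId, 0.62)
  # conserved core untouched
  expect_identical(pc[301:312], mc[301:312])
  # both records translate without internal stops
  aaPlus <- strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(unname(pair$intronPlus)))),
    "")[[1]]
  aaMinus <- strsplit(as.character(
    Biostrings::translate(Biostrings::DNAString(minus))), "")[[1]]
  expect_false("*" %in% head(aaPlus, -1))
  expect_false("*" %in% head(aaMinus, -1))
  expect_equal(nchar(pair$intronSeq), 300L)
  expect_error(genToyGenomes(syntheticConfig(genomeIdentity = 2)))
})

test_that("toy genomes round-trip through insertion detection", {
  for (s in c(3, 17, 29)) {
    pair <- genToyGenomes(syntheticConfig(seed = s, genomeIdentity = 0.6),
      flankLength = 60L)
    loc <- findIntronInsertion(pair$intronPlus, pair$intronMinus)
    expect_true(insertionDetected(loc))
    expect_equal(insertionAfter(loc), pair$insertionAfter)
    expect_identical(intronSequence(loc), pair$intronSeq)
  }
})

test_that("generators are pure: they do not disturb the global RNG", {
  set.seed(99)
  before <- runif(1)
  set.seed(99)
  cfg <- syntheticConfig(seed = 7)
  invisible(genTiterTable(cfg, c(A = 1e8)))
  invisible(genImportCounts(cfg))
  invisible(genCapsidCounts(cfg, "control"))
  invisible(genToyGenomes(cfg))
  expect_equal(runif(1), before)
})
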