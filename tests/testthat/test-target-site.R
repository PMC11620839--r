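test_that("escaper classification reproduces the printed target-site calls", {
  ctx <- codon1072Context()
  expect_equal(substr(ctx, 3214, 3216), "GAT")
  callA <- classifyEscaper(ctx, substituteAt(ctx, 3215, "C"))
  expect_equal(callA$aaChange, "D1072A")
  expect_equal(callA$position, 3215L)
  callG <- classifyEscaper(ctx, substituteAt(ctx, 3215, "G"))
  expect_equal(callG$aaChange, "D1072G")
  callY <- classifyEscaper(ctx, substituteAt(ctx, 3214, "T"))
  expect_equal(callY$aaChange, "D1072Y")
  expect_equal(callY$codonIndex, 1072L)
  expect_equal(nrow(classifyEscaper(ctx, ctx)), 0L)
  expect_error(classifyEscaper(ctx, substr(ctx, 1, 300)), "equal length")
  silent <- classifyEscaper("GATCTG", "GACCTG")
  expect_equal(silent$aaChange, "silent")
})

test_that("codon arithmetic follows the 1-based CDS convention", {
  pos <- c(1, 2, 3, 4, 3214, 3215, 3216)
  expect_equal((pos - 1) %/% 3 + 1, c(1, 1, 1, 2, 1072, 1072, 1072))
})

test_that("insertion detection recovers constructed ground truth", {
  withr::with_seed(51, {
    homolog <- .randomFixtureSeq(120)
    intron <- .randomFixtureSeq(300)
  })
  # unambiguous boundaries: the intron must not start (end) with the
  # exon base just after (before) the insertion point, otherwise the
  # insertion coordinate is intrinsically ambiguous
  pick <- function(avoid) setdiff(c("A", "C", "G", "T"), avoid)[1]
  substr(intron, 1, 1) <- pick(substr(homolog, 61, 61))
  substr(intron, 300, 300) <- pick(substr(homolog, 60, 60))
  interrupted <- paste0(substr(homolog, 1, 60), intron,
    substr(homolog, 61, 120))
  loc <- findIntronInsertion(interrupted, homolog)
  expect_true(insertionDetected(loc))
  expect_equal(insertionAfter(loc), 60L)
  expect_identical(intronSequence(loc), intron)
  # colinear sequences: no insertion, not an error
  expect_false(insertionDetected(findIntronInsertion(homolog, homolog)))
  # unrelated sequence falls below the detection threshold
  withr::with_seed(52, {
    unrelated <- .randomFixtureSeq(120)
  })
  expect_false(insertionDetected(findIntronInsertion(interrupted, unrelated)))
})

test_that("insertion recovery tolerates flank divergence", {
  exact <- 0L; close <- 0L
  for (s in 1:100) {
    pair <- genToyGenomes(syntheticConfig(seed = s, genomeIdentity = 0.8),
      flankLength = 60L)
    loc <- findIntronInsertion(pair$intronPlus, pair$intronMinus)
    d <- abs(insertionAfter(loc) - pair$insertionAfter)
    exact <- exact + (insertionDetected(loc) && d == 0L)
    close <- close + (insertionDetected(loc) && d <= 1L)
  }
  expect_equal(close, 100L)
  expect_gte(exact, 95L)
})

test_that("homologous site mapping is a fixed point on identical context", {
  withr::with_seed(53, {
    left <- .randomFixtureSeq(60)
    right <- .randomFixtureSeq(60)
  })
  site <- mapHomologousSite(NULL, c(left, right), paste0(left, right))
  expect_true(insertionDetected(site))
  expect_equal(insertionAfter(site), 61L)
  expect_equal(criticalPositions(site), c(59L, 60L))
})

test_that("site mapping finds a diverged target around a conserved core", {
  for (s in 1:20) {
    pair <- genToyGenomes(syntheticConfig(seed = s, genomeIdentity = 0.6),
      flankLength = 60L)
    plus <- unname(pair$exonPlus)
    left <- substr(plus, 1, pair$insertionAfter)
    right <- substr(plus, pair$insertionAfter + 1, nchar(plus))
    site <- mapHomologousSite(NULL, c(left, right), pair$intronMinus)
    expect_true(insertionDetected(site))
    expect_lte(abs(insertionAfter(site) - (pair$insertionAfter + 1L)), 1L)
  }
})

test_that("critical positions follow the junction geometry", {
  withr::with_seed(54, {
    filler <- .randomFixtureSeq(3156)
    left <- .randomFixtureSeq(60)
    right <- .randomFixtureSeq(60)
    tail <- .randomFixtureSeq(120)
  })
  competitor <- paste0(filler, left, right, tail)
  byDefault <- mapHomologousSite(NULL, c(left, right), competitor)
  expect_equal(insertionAfter(byDefault), 3217L)
  expect_equal(criticalPositions(byDefault), c(3215L, 3216L))
  # the PhiKZ gp178 profile: critical positions two and three bases
  # upstream of the junction (3214/3215 for a junction at 3217)
  kz <- mapHomologousSite(NULL, c(left, right), competitor,
    criticalOffsets = c(-3L, -2L))
  expect_equal(criticalPositions(kz), c(3214L, 3215L))
  expect_equal(codonIndex(kz), 1072L)
})

test_that("silent recoding changes exactly n positions, never the protein", {
  gene <- withr::with_seed(55, {
    phageHoming:::.randomCds(60)
  })
  expect_identical(recodeSilent(gene, 0), gene)
  set.seed(56)
  recoded <- recodeSilent(gene, 17)
  gc <- strsplit(gene, "")[[1]]; rc <- strsplit(recoded, "")[[1]]
  expect_equal(sum(gc != rc), 17L)
  expect_identical(
    as.character(Biostrings::translate(Biostrings::DNAString(recoded))),
    as.character(Biostrings::translate(Biostrings::DNAString(gene))))
  calls <- classifyEscaper(gene, recoded)
  expect_true(all(calls$aaChange == "silent"))
  expect_equal(nrow(calls), 17L)
  expect_error(recodeSilent(gene, 17, window = c(1, 9)), "infeasible")
})

test_that("percent identity counts alignment columns", {
  expect_equal(percentIdentity("ACGTACGT", "ACGTACGT"), 1)
  expect_equal(percentIdentity("ACGTACGT", "ACGTTCGT"), 7 / 8)
  # floor case: no common bases at equal length
  expect_lt(percentIdentity("AAAAAAAAAA", "CCCCCCCCCC"), 0.05)
  pair <- genToyGenomes(syntheticConfig(seed = 57, genomeIdentity = 0.6))
  id <- percentIdentity(pair$exonPlus, pair$intronMinus)
  expect_gte(id, 0.58)
  expect_lte(id, 0.62)
})
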