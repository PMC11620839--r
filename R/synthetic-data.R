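#' Generate a lognormal-noise plaque titer table
#'
#' Emulates the titer design of the one-round competition experiment:
#' each condition is measured in \code{nReplicates} independent
#' replicates, and plaque titers carry multiplicative (lognormal)
#' noise because they span orders of magnitude and are analyzed as
#' ratios. Each titer is \code{expected * 10^eps} with
#' \code{eps ~ Normal(0, titerLog10Sd)}.
#'
#' @param config a [SyntheticConfig-class]; \code{seed},
#'   \code{nReplicates} and \code{titerLog10Sd} are used.
#' @param expectedTiters named positive numeric vector of expected
#'   titers (PFU/ml) per condition.
#' @param strains optional named character vector mapping condition to
#'   strain label; defaults to the condition names.
#' @param experiment experiment identifier stored in the table.
#' @return A \code{data.frame} (TiterTable) with columns
#'   \code{experiment}, \code{replicate}, \code{condition},
#'   \code{strain}, \code{titer_pfu_per_ml}.
#' @examples
#' cfg <- syntheticConfig(seed = 1, titerLog10Sd = 0.2)
#' genTiterTable(cfg, c(KZ_vs_wt = 1e8, KZ_vs_del = 3.7e8))
#' @export
genTiterTable <- function(config, expectedTiters, strains = NULL,
                          experiment = "exp1") {
  stopifnot(is(config, "SyntheticConfig"))
  .assert(length(expectedTiters) >= 1L && !is.null(names(expectedTiters)),
    "expectedTiters must be a named numeric vector")
  .assert(all(expectedTiters > 0), "expected titers must be strictly positive")
  if (is.null(strains)) strains <- setNames(names(expectedTiters),
    names(expectedTiters))
  n <- config@nReplicates
  conditions <- names(expectedTiters)
  eps <- withr::with_seed(config@seed,
    rnorm(n * length(conditions), mean = 0, sd = config@titerLog10Sd))
  out <- data.frame(
    experiment = experiment,
    replicate = rep(seq_len(n), times = length(conditions)),
    condition = rep(conditions, each = n),
    strain = rep(unname(strains[conditions]), each = n),
    titer_pfu_per_ml = rep(unname(expectedTiters), each = n) * 10^eps,
    stringsAsFactors = FALSE
  )
  out
}

#' Generate nuclear protein-import classification counts
#'
#' During co-infection a fraction of phage nuclei import proteins of
#' both phages (hybrid, "co-import") while the rest import only one
#' ("distinct"). Counts are a single binomial draw over
#' \code{nNuclei} with co-import probability \code{pCoimport}
#' (defaults: 140 nuclei at 0.536).
#'
#' @param config a [SyntheticConfig-class].
#' @return Named integer vector \code{c(co = , distinct = )} summing
#'   to \code{nNuclei}.
#' @examples
#' genImportCounts(syntheticConfig(seed = 2))
#' @export
genImportCounts <- function(config) {
  stopifnot(is(config, "SyntheticConfig"))
  n <- config@nNuclei
  .assert(n >= 1L, "nNuclei must be >= 1")
  co <- withr::with_seed(config@seed,
    stats::rbinom(1L, size = n, prob = config@pCoimport))
  c(co = as.integer(co), distinct = as.integer(n - co))
}

#' Generate per-tomogram DNA-filled capsid counts
#'
#' Counts of DNA-filled capsids per tomogram are drawn from a
#' negative binomial with the configured condition mean and a shared
#' dispersion (size) parameter, so both the control regime
#' (mean ~22.6) and the near-zero endonuclease-treated regime
#' (mean ~0.76) come from one family. \code{capsidDispersion = Inf}
#' gives the Poisson limit.
#'
#' @param config a [SyntheticConfig-class].
#' @param condition \code{"control"} or \code{"treated"}.
#' @param n number of tomograms; defaults to 5 (control) or 17
#'   (treated), the tomogram counts of the imaging experiment.
#' @return integer vector of non-negative counts, one per tomogram.
#' @examples
#' genCapsidCounts(syntheticConfig(seed = 3), "treated")
#' @export
genCapsidCounts <- function(config, condition = c("control", "treated"),
                            n = NULL) {
  stopifnot(is(config, "SyntheticConfig"))
  condition <- match.arg(condition)
  m <- if (condition == "control") config@capsidMeanControl else
    config@capsidMeanTreated
  .assert(m >= 0, "capsid mean must be >= 0")
  if (is.null(n)) n <- if (condition == "control") 5L else 17L
  if (m == 0) return(integer(n))
  withr::with_seed(config@seed, {
    if (is.finite(config@capsidDispersion)) {
      as.integer(rnbinom(n, mu = m, size = config@capsidDispersion))
    } else {
      as.integer(rpois(n, lambda = m))
    }
  })
}

#' Generate an escaper substitution spectrum
#'
#' Draws \code{nEscapers} independent escaper mutants from the
#' configured multinomial over (position, alternative base) classes.
#' The default spectrum mirrors the observed escapers: 14/17 at
#' nucleotide 3215 of the competitor vRNAP gene and 3/17 at 3214.
#'
#' @param nEscapers number of escaper mutants to draw (0 allowed).
#' @param config a [SyntheticConfig-class].
#' @return data.frame with one row per escaper and columns
#'   \code{position}, \code{ref}, \code{alt}.
#' @examples
#' genEscaperSpectrum(17, syntheticConfig(seed = 4))
#' @export
genEscaperSpectrum <- function(nEscapers, config) {
  stopifnot(is(config, "SyntheticConfig"))
  .assert(nEscapers >= 0, "nEscapers must be >= 0")
  sp <- config@escaperSiteProbs
  .assert(nrow(sp) > 0L, "escaperSiteProbs must be non-empty")
  if (nEscapers == 0L) {
    return(data.frame(position = integer(0), ref = character(0),
      alt = character(0), stringsAsFactors = FALSE))
  }
  counts <- withr::with_seed(config@seed,
    rmultinom(1L, size = nEscapers, prob = sp$prob)[, 1L])
  idx <- rep(seq_len(nrow(sp)), times = counts)
  data.frame(position = sp$position[idx], ref = sp$ref[idx],
    alt = sp$alt[idx], stringsAsFactors = FALSE)
}

#' Generate a toy intron(+)/intron(-) gene pair
#'
#' Builds a pair of protein-coding sequences emulating the two
#' phages' virion RNA polymerase alleles: a shared, perfectly
#' conserved core of \code{coreLength} nt straddles the designated
#' intron insertion point (the target region is highly conserved
#' among related phages) while the flanks diverge to the configured
#' identity. The intron(+) record carries an intron of
#' \code{intronLength} nt at the insertion point; the intron(-)
#' homolog is uninterrupted. Mutations are placed codon-aware so both
#' records translate without internal stop codons (for the unspliced
#' intron(+) record this additionally requires \code{intronLength}
#' divisible by 3, as in the default).
#'
#' The intron's first and last bases are constrained to differ from
#' the adjacent exon bases; without this the insertion coordinate is
#' genuinely ambiguous (inserting \code{Gxx} before a \code{G} is
#' indistinguishable from inserting \code{xxG} after it) and no
#' detector could recover it exactly.
#'
#' @param config a [SyntheticConfig-class]; \code{seed},
#'   \code{genomeIdentity} and \code{intronLength} are used.
#' @param flankLength exon flank length (nt) on each side of the core;
#'   must be a multiple of 3 (default 300).
#' @param coreLength length of the fully conserved core around the
#'   insertion point; must be a multiple of 6 so the insertion point
#'   at its midpoint falls on a codon boundary (default 12).
#' @return A list with elements \code{intronPlus} and
#'   \code{intronMinus} (named character sequences), \code{exonPlus}
#'   (the intron(+) record with the intron spliced out),
#'   \code{intronSeq}, \code{insertionAfter} (1-based position on
#'   \code{intronPlus} and \code{exonPlus}) and \code{coreRange}.
#' @examples
#' pair <- genToyGenomes(syntheticConfig(seed = 5, genomeIdentity = 0.6))
#' pair$insertionAfter
#' @export
genToyGenomes <- function(config, flankLength = 300L, coreLength = 12L) {
  stopifnot(is(config, "SyntheticConfig"))
  id <- config@genomeIdentity
  .assert(id >= 0 && id <= 1, "genomeIdentity must be in [0, 1]")
  intronLength <- config@intronLength
  .assert(intronLength >= 0L, "intronLength must be >= 0")
  .assert(flankLength %% 3L == 0L && flankLength >= 3L,
    "flankLength must be a positive multiple of 3")
  .assert(coreLength %% 6L == 0L && coreLength >= 6L,
    "coreLength must be a positive multiple of 6")
  withr::with_seed(config@seed, {
    exonLen <- 2L * flankLength + coreLength
    exon <- .randomCds(exonLen %/% 3L)
    insertionAfter <- flankLength + coreLength %/% 2L
    coreRange <- c(flankLength + 1L, flankLength + coreLength)

    # diverge the flanks of the intron(-) homolog to the target identity
    flankPos <- c(seq_len(flankLength), (coreRange[2] + 1L):exonLen)
    nMut <- round((1 - id) * length(flankPos))
    minus <- exon
    if (nMut > 0L) {
      mutAt <- sort(sample(flankPos, nMut))
      for (p in mutAt) minus <- .mutateNoStop(minus, p)
    }

    intron <- ""
    plus <- exon
    if (intronLength > 0L) {
      intron <- if (intronLength %% 3L == 0L) {
        .randomCds(intronLength %/% 3L)
      } else {
        paste(sample(DNA_BASES, intronLength, replace = TRUE), collapse = "")
      }
      # unambiguous boundaries: intron ends must differ from adjacent
      # exon bases (and stay stop-free when in frame)
      leftNbr <- substr(exon, insertionAfter, insertionAfter)
      rightNbr <- substr(exon, insertionAfter + 1L, insertionAfter + 1L)
      if (substr(intron, 1L, 1L) == rightNbr)
        intron <- .mutateNoStop(intron, 1L, avoid = rightNbr)
      if (substr(intron, intronLength, intronLength) == leftNbr)
        intron <- .mutateNoStop(intron, intronLength, avoid = leftNbr)
      plus <- paste0(substr(exon, 1L, insertionAfter), intron,
        substr(exon, insertionAfter + 1L, exonLen))
    }
    list(
      intronPlus = c(intron_plus = plus),
      intronMinus = c(intron_minus = minus),
      exonPlus = c(exon_plus = exon),
      intronSeq = intron,
      insertionAfter = insertionAfter,
      coreRange = coreRange
    )
  })
}
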