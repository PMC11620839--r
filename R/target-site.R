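# Sequence-level genetics of the homing system: insertion-point
# detection, homologous target mapping, escaper classification and
# silent recoding. Coordinates are 1-based inclusive, CDS frame from
# position 1 (nucleotide 3214 is the first base of codon 1072).

#' @noRd
.seqName <- function(x, default) {
  nm <- NULL
  if (is(x, "DNAStringSet")) nm <- names(x)
  if (is.character(x)) nm <- names(x)
  if (is.null(nm) || !nzchar(nm[1L])) default else nm[1L]
}

#' Locate an intron insertion by split alignment against a homolog
#'
#' Finds the maximal-scoring partition of the uninterrupted homolog
#' into a prefix matching the interrupted gene's left flank and a
#' suffix matching its right flank. The two flank alignments are
#' split-consistent: the homolog is cut at a single point, the left
#' part aligned with both starts anchored (free end) and the right
#' part with both ends anchored (free start), and the cut maximizing
#' the combined affine-gap score determines the insertion point on
#' the interrupted gene; the intervening sequence is the intron.
#' Ties break to the leftmost insertion point, which also resolves
#' the intrinsic ambiguity when an intron boundary base repeats the
#' adjacent exon base.
#'
#' @param interrupted the intron(+) (interrupted) gene: character
#'   string, \code{DNAString} or length-1 \code{DNAStringSet}.
#' @param homolog the uninterrupted intron(-) homolog.
#' @param match,mismatch,gapOpen,gapExt affine-gap alignment scores;
#'   a gap of length L costs \code{gapOpen + L * gapExt}.
#' @param thresholdFrac detection threshold as a fraction of the
#'   maximum attainable score (\code{match * nchar(homolog)}); below
#'   it a non-detected [IntronLocus-class] is returned (distinct
#'   from an error). The default 0.2 accepts flanks down to ~50%
#'   identity (score fraction 0.25 under the default scores) while
#'   rejecting unrelated sequence (expected score fraction < 0).
#' @return An [IntronLocus-class]; \code{insertionDetected()} is
#'   \code{FALSE} when the sequences are colinear (no intron) or no
#'   flank alignment clears the threshold.
#' @examples
#' homolog <- paste(rep("ACGTTGCAGT", 12), collapse = "")
#' intron <- paste(rep("TTAACGGCCA", 5), collapse = "")
#' interrupted <- paste0(substr(homolog, 1, 60), intron,
#'   substr(homolog, 61, 120))
#' findIntronInsertion(interrupted, homolog)
#' @export
findIntronInsertion <- function(interrupted, homolog,
                                match = 2, mismatch = -1,
                                gapOpen = -4, gapExt = -1,
                                thresholdFrac = 0.2) {
  name <- .seqName(interrupted, "interrupted_gene")
  iChr <- .asDnaChr(interrupted, "interrupted")
  hChr <- .asDnaChr(homolog, "homolog")
  m <- nchar(iChr); n <- nchar(hChr)
  notDetected <- function(score) new("IntronLocus", hostGene = name,
    insertionAfter = 0L, intronSequence = "", detected = FALSE,
    score = score)
  if (n < 2L || m < 2L) return(notDetected(NA_real_))

  fwd <- .flankDp(iChr, hChr, TRUE, match, mismatch, gapOpen, gapExt)
  bwd <- .flankDp(.revChr(iChr), .revChr(hChr), TRUE,
    match, mismatch, gapOpen, gapExt)
  M1 <- fwd$colmax; i1 <- fwd$argi
  M2 <- rev(bwd$colmax)          # M2[j]: homolog[j..n] vs suffix of gene
  i2 <- m - rev(bwd$argi) + 1L   # gene position aligned to homolog[j]

  js <- seq_len(n - 1L)
  total <- M1[js] + M2[js + 1L]
  ord <- order(-total, js)       # best score first, leftmost split on ties
  threshold <- thresholdFrac * match * n
  for (j in ord) {
    if (!is.finite(total[j]) || total[j] < threshold) break
    iL <- i1[j]; iR <- i2[j + 1L]
    if (is.na(iL) || is.na(iR) || iR <= iL) next
    if (iR == iL + 1L) return(notDetected(total[j]))  # colinear, no intron
    return(new("IntronLocus", hostGene = name,
      insertionAfter = as.integer(iL),
      intronSequence = substr(iChr, iL + 1L, iR - 1L),
      detected = TRUE, score = total[j]))
  }
  notDetected(if (length(total)) max(total) else NA_real_)
}

#' Map the homologous target site on a competitor gene
#'
#' Aligns the donor's exon-junction context (the left and right
#' flanks of the intron insertion point) to a competitor gene and
#' returns the competitor coordinate aligning with the junction. The
#' left flank is aligned with a free start and its end anchored at
#' each candidate coordinate; the right flank symmetrically; the
#' coordinate maximizing the combined score is the junction. By
#' default the critical (escape-conferring) positions are the two
#' nucleotides immediately upstream of the junction-aligned position
#' (offsets -2, -1); gene-specific profiles can override the offsets
#' — e.g. the PhiKZ gp178 geometry places them at offsets -3, -2
#' (junction 3217, critical positions 3214 and 3215).
#'
#' @param locus optional [IntronLocus-class] providing provenance
#'   (not used in the computation).
#' @param donorFlanks character vector of length 2: the donor's left
#'   and right exon flanks around the insertion point.
#' @param competitor the competitor gene sequence.
#' @param criticalOffsets integer offsets relative to the
#'   junction-aligned position, default \code{c(-2L, -1L)}.
#' @param match,mismatch,gapOpen,gapExt alignment scores.
#' @param thresholdFrac per-flank detection threshold as a fraction
#'   of each flank's maximum attainable score.
#' @return A [TargetSite-class]; not detected when either flank
#'   alignment falls below threshold.
#' @examples
#' left <- paste(rep("ACGTTGCAGT", 6), collapse = "")
#' right <- paste(rep("CTTGAACGGT", 6), collapse = "")
#' site <- mapHomologousSite(NULL, c(left, right), paste0(left, right))
#' insertionAfter(site)  # junction coordinate 61
#' @export
mapHomologousSite <- function(locus = NULL, donorFlanks, competitor,
                              criticalOffsets = c(-2L, -1L),
                              match = 2, mismatch = -1,
                              gapOpen = -4, gapExt = -1,
                              thresholdFrac = 0.2) {
  .assert(length(donorFlanks) == 2L,
    "donorFlanks must contain a left and a right flank")
  left <- .asDnaChr(donorFlanks[[1L]], "left flank")
  right <- .asDnaChr(donorFlanks[[2L]], "right flank")
  name <- .seqName(competitor, "competitor_gene")
  comp <- .asDnaChr(competitor, "competitor")
  m <- nchar(comp)
  notFound <- function(score) new("TargetSite", gene = name,
    insertionHomologPosition = 0L, criticalPositions = integer(0),
    codonIndex = 0L, detected = FALSE, score = score)
  if (m < 2L) return(notFound(NA_real_))

  L2 <- .flankDp(comp, left, FALSE, match, mismatch, gapOpen, gapExt)$lastcol
  R2 <- rev(.flankDp(.revChr(comp), .revChr(right), FALSE,
    match, mismatch, gapOpen, gapExt)$lastcol)

  is <- seq_len(m - 1L)
  total <- L2[is] + R2[is + 1L]
  iStar <- which.max(total)      # leftmost on ties
  if (!is.finite(total[iStar])) return(notFound(NA_real_))
  okL <- L2[iStar] >= thresholdFrac * match * nchar(left)
  okR <- R2[iStar + 1L] >= thresholdFrac * match * nchar(right)
  if (!okL || !okR) return(notFound(total[iStar]))

  junction <- iStar + 1L         # competitor base aligned to right flank start
  crit <- sort(as.integer(junction + criticalOffsets))
  crit <- crit[crit >= 1L & crit <= m]
  codon <- if (length(crit)) (crit[1L] - 1L) %/% 3L + 1L else 0L
  new("TargetSite", gene = name,
    insertionHomologPosition = as.integer(junction),
    criticalPositions = crit, codonIndex = as.integer(codon),
    detected = TRUE, score = total[iStar])
}

#' Classify escaper substitutions against a reference gene
#'
#' Reports every substitution between two equal-length, in-frame
#' coding sequences with its codon index
#' (\code{floor((pos - 1) / 3) + 1}) and the amino-acid change
#' obtained by translating the full reference and mutant codons
#' under the standard genetic code; synonymous changes are labelled
#' \code{"silent"}. Indels are out of scope: a length mismatch is an
#' error, not a realignment.
#'
#' @param reference,mutant equal-length CDS sequences (character,
#'   \code{DNAString} or length-1 \code{DNAStringSet}); length must
#'   be divisible by 3.
#' @return data.frame with columns \code{position}, \code{ref},
#'   \code{alt}, \code{codonIndex}, \code{aaChange} (labels like
#'   \code{"D1072A"}, or \code{"silent"}); zero rows when the
#'   sequences are identical.
#' @examples
#' ref <- "ATGGATGAT"
#' mut <- "ATGGCTGAT"
#' classifyEscaper(ref, mut) # D2A
#' @export
classifyEscaper <- function(reference, mutant) {
  ref <- .asDnaChr(reference, "reference")
  mut <- .asDnaChr(mutant, "mutant")
  .assert(nchar(ref) == nchar(mut),
    "reference and mutant must have equal length (indels out of scope)")
  .assert(nchar(ref) %% 3L == 0L, "sequences must be in frame (length %% 3 == 0)")
  r <- strsplit(ref, "", fixed = TRUE)[[1L]]
  m <- strsplit(mut, "", fixed = TRUE)[[1L]]
  pos <- which(r != m)
  if (!length(pos)) {
    return(data.frame(position = integer(0), ref = character(0),
      alt = character(0), codonIndex = integer(0),
      aaChange = character(0), stringsAsFactors = FALSE))
  }
  codonIdx <- (pos - 1L) %/% 3L + 1L
  gc <- Biostrings::GENETIC_CODE
  aa <- vapply(codonIdx, function(ci) {
    s <- 3L * (ci - 1L) + 1L
    refAA <- unname(gc[substr(ref, s, s + 2L)])
    mutAA <- unname(gc[substr(mut, s, s + 2L)])
    if (refAA == mutAA) "silent" else paste0(refAA, ci, mutAA)
  }, character(1L))
  data.frame(position = pos, ref = r[pos], alt = m[pos],
    codonIndex = codonIdx, aaChange = aa, stringsAsFactors = FALSE)
}

#' Introduce silent (synonymous) substitutions into a CDS window
#'
#' Returns a sequence differing from the input at exactly
#' \code{nMutations} positions, all inside \code{window}, with an
#' identical translation — the strategy used to recode a target gene
#' so an endonuclease no longer recognizes it while the protein is
#' unchanged. At most one substitution is placed per codon, each
#' chosen uniformly among that codon's synonymous single-base
#' variants. Consumes the current RNG stream; seed the RNG for
#' reproducibility.
#'
#' @param gene an in-frame CDS.
#' @param nMutations number of silent substitutions (0 allowed).
#' @param window integer length-2 range of nucleotide positions
#'   (1-based inclusive) within which substitutions must fall;
#'   default the whole gene.
#' @return character CDS of the same length.
#' @examples
#' set.seed(1)
#' g <- paste(rep("GATCTGAAA", 20), collapse = "")
#' r <- recodeSilent(g, 17)
#' sum(strsplit(g, "")[[1]] != strsplit(r, "")[[1]]) # 17
#' @export
recodeSilent <- function(gene, nMutations, window = NULL) {
  g <- .asDnaChr(gene, "gene")
  len <- nchar(g)
  .assert(len %% 3L == 0L, "gene must be in frame (length %% 3 == 0)")
  .assert(nMutations >= 0, "nMutations must be >= 0")
  if (is.null(window)) window <- c(1L, len)
  .assert(length(window) == 2L && window[1L] >= 1L && window[2L] <= len &&
    window[1L] <= window[2L], "window must lie within the gene")
  if (nMutations == 0L) return(g)

  gc <- Biostrings::GENETIC_CODE
  codons <- .codons(g)
  nCodon <- length(codons)
  inWindow <- which(3L * seq_len(nCodon) - 2L >= window[1L] &
    3L * seq_len(nCodon) <= window[2L])
  # synonymous single-base variants per in-window codon
  cands <- lapply(inWindow, function(ci) {
    codon <- codons[ci]
    out <- list()
    for (off in 1:3) {
      cur <- substr(codon, off, off)
      for (b in setdiff(DNA_BASES, cur)) {
        alt <- codon
        substr(alt, off, off) <- b
        if (identical(unname(gc[alt]), unname(gc[codon]))) {
          out[[length(out) + 1L]] <- c(pos = 3L * (ci - 1L) + off, base = b)
        }
      }
    }
    out
  })
  feasible <- inWindow[vapply(cands, length, integer(1L)) > 0L]
  if (nMutations > length(feasible)) {
    stop(sprintf(
      "infeasible: window supports at most %d silent single-site substitutions (one per codon), %d requested",
      length(feasible), nMutations), call. = FALSE)
  }
  pick <- sort(sample(length(feasible), nMutations))
  out <- g
  for (kk in pick) {
    opts <- cands[[match(feasible[kk], inWindow)]]
    choice <- opts[[sample.int(length(opts), 1L)]]
    p <- as.integer(choice[["pos"]])
    substr(out, p, p) <- choice[["base"]]
  }
  out
}

#' Global-alignment percent identity of two sequences
#'
#' Needleman-Wunsch global alignment (via Biostrings) followed by a
#' column count: identity = matching columns / total alignment
#' columns, with gap columns counting as mismatches.
#'
#' @param a,b non-empty nucleotide sequences.
#' @param match,mismatch,gapOpen,gapExt alignment scores (penalties
#'   are passed to Biostrings as positive costs).
#' @return fraction between 0 and 1.
#' @examples
#' percentIdentity("ACGTACGT", "ACGTTCGT") # 0.875
#' @export
percentIdentity <- function(a, b, match = 2, mismatch = -1,
                            gapOpen = -4, gapExt = -1) {
  aChr <- .asDnaChr(a, "a"); bChr <- .asDnaChr(b, "b")
  mat <- Biostrings::nucleotideSubstitutionMatrix(match = match,
    mismatch = mismatch, baseOnly = TRUE)
  aln <- Biostrings::pairwiseAlignment(aChr, bChr, type = "global",
    substitutionMatrix = mat, gapOpening = abs(gapOpen),
    gapExtension = abs(gapExt))
  p <- strsplit(as.character(Biostrings::alignedPattern(aln)), "")[[1L]]
  s <- strsplit(as.character(Biostrings::alignedSubject(aln)), "")[[1L]]
  sum(p == s & p != "-") / length(p)
}
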