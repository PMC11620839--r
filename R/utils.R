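# internal helpers shared across modules

STOP_CODONS <- c("TAA", "TAG", "TGA")
DNA_BASES <- c("A", "C", "G", "T")

#' @noRd
.assert <- function(cond, msg) if (!isTRUE(cond)) stop(msg, call. = FALSE)

# round half up at `digits`; base round() is round-half-even
#' @noRd
.roundHalfUp <- function(x, digits = 1) {
  p <- 10^digits
  floor(x * p + 0.5) / p
}

# accept character / DNAString / length-1 DNAStringSet, return upper chr
#' @noRd
.asDnaChr <- function(x, what = "sequence") {
  if (is(x, "DNAStringSet")) {
    .assert(length(x) == 1L, paste(what, "must be a single sequence"))
    x <- x[[1L]]
  }
  if (is(x, "DNAString")) x <- as.character(x)
  .assert(is.character(x) && length(x) == 1L,
    paste(what, "must be a single character string or DNAString"))
  x <- toupper(unname(x))
  .assert(nchar(x) > 0L, paste(what, "must be non-empty"))
  .assert(!grepl("[^ACGT]", x),
    paste(what, "may only contain A, C, G, T (no ambiguity codes)"))
  x
}

#' @noRd
.revChr <- function(x) {
  paste(rev(strsplit(x, "", fixed = TRUE)[[1L]]), collapse = "")
}

#' @noRd
.translateChr <- function(x) {
  .assert(nchar(x) %% 3L == 0L, "CDS length must be divisible by 3")
  as.character(Biostrings::translate(Biostrings::DNAString(x)))
}

# codons of a CDS string, in order
#' @noRd
.codons <- function(x) {
  n <- nchar(x) %/% 3L
  substring(x, 3L * seq_len(n) - 2L, 3L * seq_len(n))
}

# sample a random in-frame CDS with no stop codons; consumes the RNG
#' @noRd
.randomCds <- function(nCodons) {
  codons <- apply(
    matrix(sample(DNA_BASES, 3L * nCodons, replace = TRUE), ncol = 3L),
    1L, paste, collapse = "")
  bad <- codons %in% STOP_CODONS
  while (any(bad)) {
    codons[bad] <- vapply(which(bad), function(i)
      paste(sample(DNA_BASES, 3L, replace = TRUE), collapse = ""),
      character(1L))
    bad <- codons %in% STOP_CODONS
  }
  paste(codons, collapse = "")
}

# substitute position `pos` of CDS `x` with a base != current that does
# not create a stop codon; `avoid` optionally excludes further bases
#' @noRd
.mutateNoStop <- function(x, pos, avoid = character(0)) {
  cur <- substr(x, pos, pos)
  codonIdx <- (pos - 1L) %/% 3L + 1L
  codonStart <- 3L * (codonIdx - 1L) + 1L
  codon <- substr(x, codonStart, codonStart + 2L)
  offset <- pos - codonStart + 1L
  cands <- setdiff(DNA_BASES, c(cur, avoid))
  ok <- vapply(cands, function(b) {
    newCodon <- codon
    substr(newCodon, offset, offset) <- b
    !(newCodon %in% STOP_CODONS)
  }, logical(1L))
  cands <- cands[ok]
  .assert(length(cands) > 0L, "no stop-free substitution available")
  b <- if (length(cands) == 1L) cands else sample(cands, 1L)
  substr(x, pos, pos) <- b
  x
}
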