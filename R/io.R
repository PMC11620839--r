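# Tabular and sequence I/O. Every text artifact carries a comment
# header with the package version and seed, so outputs are
# self-documenting and reproducible.

#' @noRd
.headerLines <- function(seed = NULL) {
  v <- as.character(utils::packageVersion("phageHoming"))
  c(sprintf("# phageHoming %s", v),
    if (!is.null(seed)) sprintf("# seed: %d", as.integer(seed)))
}

#' Write a titer table as TSV
#'
#' Writes the table with a comment header recording the package
#' version and, when given, the generating seed.
#'
#' @param table a TiterTable data.frame, see [genTiterTable()].
#' @param path output file path.
#' @param seed optional integer seed recorded in the header.
#' @return \code{path}, invisibly.
#' @export
writeTiterTable <- function(table, path, seed = NULL) {
  .assert(is.data.frame(table), "table must be a data.frame")
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.headerLines(seed), con)
  write.table(table, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a titer table written by [writeTiterTable()]
#'
#' Comment lines starting with \code{#} are skipped. Titers must be
#' strictly positive and (experiment, replicate, condition, strain)
#' unique.
#'
#' @param path TSV file path.
#' @return data.frame with the TiterTable columns.
#' @export
readTiterTable <- function(path) {
  tb <- read.table(path, header = TRUE, sep = "\t", comment.char = "#",
    stringsAsFactors = FALSE)
  .assert(all(c("experiment", "replicate", "condition", "strain",
    "titer_pfu_per_ml") %in% names(tb)),
    "missing TiterTable columns")
  .assert(all(tb$titer_pfu_per_ml > 0), "titers must be strictly positive")
  key <- paste(tb$experiment, tb$replicate, tb$condition, tb$strain)
  .assert(!anyDuplicated(key),
    "(experiment, replicate, condition, strain) must be unique")
  tb
}

#' Write named sequences as FASTA
#'
#' @param sequences named character vector (or \code{DNAStringSet})
#'   of nucleotide sequences.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeGenesFasta <- function(sequences, path) {
  if (!is(sequences, "DNAStringSet"))
    sequences <- Biostrings::DNAStringSet(unlist(sequences))
  Biostrings::writeXStringSet(sequences, path)
  invisible(path)
}

#' Read gene sequences from FASTA
#'
#' @param path FASTA file path.
#' @return named character vector of sequences.
#' @export
readGenesFasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  setNames(as.character(x), names(x))
}

#' Write escaper calls as TSV
#'
#' A deliberately minimal, VCF-inspired table: position, ref, alt,
#' codon index, amino-acid change.
#'
#' @param calls data.frame from [classifyEscaper()].
#' @param path output file path.
#' @param seed optional seed recorded in the header.
#' @return \code{path}, invisibly.
#' @export
writeEscaperCalls <- function(calls, path, seed = NULL) {
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(.headerLines(seed), con)
  write.table(calls, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
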