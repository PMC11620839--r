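# Independently coded brute-force oracles for the assay statistics,
# plus small fixture builders. These deliberately use only elementary
# arithmetic so they stay independent of the implementation they check.

oracleGeomMeanPercent <- function(ratios) {
  prod(ratios)^(1 / length(ratios)) * 100
}

oracleOneSampleT <- function(x) {
  n <- length(x)
  t <- mean(x) / (sqrt(sum((x - mean(x))^2) / (n - 1)) / sqrt(n))
  p <- 2 * stats::pt(-abs(t), df = n - 1)
  list(t = t, p = p)
}

oraclePooledT <- function(a, b) {
  na <- length(a); nb <- length(b)
  sp2 <- (sum((a - mean(a))^2) + sum((b - mean(b))^2)) / (na + nb - 2)
  t <- (mean(a) - mean(b)) / sqrt(sp2 * (1 / na + 1 / nb))
  p <- 2 * stats::pt(-abs(t), df = na + nb - 2)
  list(t = t, p = p)
}

oracleMeanSem <- function(x) {
  n <- length(x)
  m <- sum(x) / n
  s <- sqrt(sum((x - m)^2) / (n - 1))
  list(mean = m, sem = s / sqrt(n))
}

randomTiters <- function(n, seed) {
  withr::with_seed(seed, 10^stats::runif(n, 3, 9))
}

# CDS with codon 1072 = GAT (Asp) spanning nucleotides 3214-3216,
# long enough to classify escaper substitutions at 3214/3215
codon1072Context <- function() {
  paste0(paste(rep("GAAGAT", 535), collapse = ""), "GATGAT",
    paste(rep("GAAGAT", 65), collapse = ""))
}

substituteAt <- function(seq, pos, base) {
  substr(seq, pos, pos) <- base
  seq
}

.randomFixtureSeq <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}
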