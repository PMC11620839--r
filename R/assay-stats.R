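# Summary statistics for plaque-titer tables and count data, as used
# in spot-titer and tomogram-count assays.

#' Efficiency of plating
#'
#' Per-pair ratio of test over control titers, summarized as the
#' geometric mean of the ratios expressed in percent. Ratios are
#' analyzed on the log scale throughout the package, so the
#' geometric (not arithmetic) mean is the natural summary; the
#' per-pair ratios are always reported alongside. When
#' \code{paired = TRUE} and at least two pairs are available, a
#' ratio-paired t-test (see [ratioPairedTTest()]) is attached.
#'
#' @param test,control strictly positive titer vectors; equal length
#'   required when \code{paired = TRUE}.
#' @param paired are the measurements paired (default TRUE, the spot
#'   titer design where each test plate is normalized to its paired
#'   control plate)?
#' @return An object of class \code{"EopResult"}: a list with
#'   \code{perPairRatios}, \code{eopPercent}, \code{tStatistic},
#'   \code{pValue}, \code{nPairs}.
#' @examples
#' efficiencyOfPlating(c(1e3, 2e3, 1.5e3), c(1e8, 1e8, 2e8))
#' @export
efficiencyOfPlating <- function(test, control, paired = TRUE) {
  .assert(all(test > 0) && all(control > 0),
    "all titers must be strictly positive")
  if (paired) {
    .assert(length(test) == length(control),
      "paired EOP requires equal-length test and control vectors")
    ratios <- test / control
  } else {
    ratios <- test / mean(control)
  }
  eop <- exp(mean(log(ratios))) * 100
  tt <- list(statistic = NA_real_, p.value = NA_real_)
  if (paired && length(test) >= 2L) {
    tt <- ratioPairedTTest(test, control)
    tt <- list(statistic = tt$t, p.value = tt$p)
  }
  structure(list(
    perPairRatios = ratios,
    eopPercent = eop,
    tStatistic = tt$statistic,
    pValue = tt$p.value,
    nPairs = length(ratios)
  ), class = "EopResult")
}

#' @export
print.EopResult <- function(x, ...) {
  cat(sprintf("EOP = %.4g%% (geometric mean of %d ratios)\n",
    x$eopPercent, x$nPairs))
  if (!is.na(x$tStatistic))
    cat(sprintf("ratio paired t-test: t = %.4g, p = %.4g\n",
      x$tStatistic, x$pValue))
  invisible(x)
}

#' Per-replicate fold-change against the mean of a control arm
#'
#' Each experimental titer is divided by the arithmetic mean of the
#' control titers, the convention of the one-round competition
#' analysis.
#'
#' @param experimental strictly positive experimental titers.
#' @param control strictly positive, non-empty control titers.
#' @return numeric vector of per-replicate fold-changes.
#' @examples
#' foldChange(c(2, 4, 6), c(2, 2, 2))
#' @export
foldChange <- function(experimental, control) {
  .assert(length(control) >= 1L, "control must be non-empty")
  .assert(all(experimental > 0) && all(control > 0),
    "all titers must be strictly positive")
  experimental / mean(control)
}

#' Ratio-paired t-test
#'
#' A paired t-test on log-transformed titers: a one-sample two-sided
#' t-test of \code{log10(test/control)} against 0 with N - 1 degrees
#' of freedom. The log base does not affect t or p. This is the
#' standard "ratio paired t-test" of common statistics packages.
#'
#' @param test,control strictly positive paired titers, length >= 2.
#' @return list with \code{t}, \code{p}, \code{df}, \code{n}.
#' @examples
#' ratioPairedTTest(c(1e3, 2e3, 1.2e3), c(1e8, 0.8e8, 1.1e8))
#' @export
ratioPairedTTest <- function(test, control) {
  .assert(length(test) == length(control),
    "test and control must have equal length")
  .assert(length(test) >= 2L, "at least two pairs required")
  .assert(all(test > 0) && all(control > 0),
    "all titers must be strictly positive")
  lr <- log10(test / control)
  if (sd(lr) == 0) {
    # all ratios identical; t is 0 when the common log-ratio is 0
    t <- if (all(lr == 0)) 0 else sign(mean(lr)) * Inf
    p <- if (t == 0) 1 else 0
    return(list(t = t, p = p, df = length(lr) - 1L, n = length(lr)))
  }
  ht <- t.test(lr, mu = 0)
  list(t = unname(ht$statistic), p = ht$p.value,
    df = unname(ht$parameter), n = length(lr))
}

#' Two-sample t-test on group values
#'
#' Two-sided Student t-test with pooled variance by default (the
#' variant is not fixed by convention; Welch's correction is
#' available via \code{welch = TRUE}).
#'
#' @param a,b numeric vectors, each of length >= 2.
#' @param welch use the Welch unequal-variance form?
#' @return list with \code{t}, \code{p}, \code{df}.
#' @examples
#' unpairedTTest(rnorm(5), rnorm(5, 2))
#' @export
unpairedTTest <- function(a, b, welch = FALSE) {
  .assert(length(a) >= 2L && length(b) >= 2L,
    "each group needs at least two values")
  if (sd(c(a, b)) == 0) {
    return(list(t = 0, p = 1, df = length(a) + length(b) - 2L))
  }
  ht <- t.test(a, b, var.equal = !welch)
  list(t = unname(ht$statistic), p = ht$p.value,
    df = unname(ht$parameter))
}

#' Summarize per-tomogram capsid counts
#'
#' @param counts non-negative integer counts, one per tomogram.
#' @return list with \code{mean}, \code{sem} (\code{NA} for a single
#'   tomogram) and \code{n}.
#' @examples
#' capsidCountSummary(c(rep(1, 13), rep(0, 4)))
#' @export
capsidCountSummary <- function(counts) {
  .assert(length(counts) >= 1L, "counts must be non-empty")
  .assert(all(counts >= 0), "counts must be non-negative")
  n <- length(counts)
  list(
    mean = mean(counts),
    sem = if (n >= 2L) sd(counts) / sqrt(n) else NA_real_,
    n = n
  )
}

#' Percent decrease of a treated mean relative to a control mean
#'
#' \code{100 * (1 - meanTreated / meanControl)}, rounded half-up to
#' one decimal, the convention used for reporting virion-production
#' decreases.
#'
#' @param meanControl positive control mean.
#' @param meanTreated non-negative treated mean.
#' @return percent decrease, one decimal.
#' @examples
#' percentDecrease(22.6, 0.76) # 96.6
#' @export
percentDecrease <- function(meanControl, meanTreated) {
  .assert(meanControl > 0, "control mean must be > 0")
  .assert(meanTreated >= 0, "treated mean must be >= 0")
  .roundHalfUp(100 * (1 - meanTreated / meanControl), 1)
}

#' Nuclear import fractions during co-infection
#'
#' Converts co-import/distinct-import nucleus counts into percentages
#' rounded half-up to one decimal.
#'
#' @param counts numeric of length 2: co-import and distinct-import
#'   counts, in that order (e.g. the output of [genImportCounts()]).
#' @return named numeric \code{c(coImportPercent, distinctPercent)}.
#' @examples
#' importFractions(c(co = 75, distinct = 65)) # 53.6 / 46.4
#' @export
importFractions <- function(counts) {
  .assert(length(counts) == 2L, "counts must have length 2 (co, distinct)")
  .assert(all(counts >= 0), "counts must be non-negative")
  total <- sum(counts)
  .assert(total >= 1, "total nucleus count must be >= 1")
  c(coImportPercent = .roundHalfUp(100 * counts[[1L]] / total, 1),
    distinctPercent = .roundHalfUp(100 * counts[[2L]] / total, 1))
}
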