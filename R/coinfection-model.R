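# Stochastic per-cell model of co-infection interference competition.
#
# Per cell, strain counts are independent Poisson(MOI). The intron(+)
# strain A always bursts when present. The intron(-) strain B is
# eliminated from a co-infected cell when a hybrid nucleus forms AND
# the site is not pre-escaped AND cleavage succeeds AND recombination
# rescue fails; the effective per-co-infection interference
# probability is q = h * k * (1 - mu) * (1 - rEff).

# effective rescue probability under the hard identity threshold
#' @noRd
.rEff <- function(params) {
  if (!params@compartmentalized &&
      params@identity >= params@identityThreshold) params@rMax else 0
}

#' Effective interference probability q
#'
#' \code{q = h * k * (1 - mu) * (1 - rEff)}: the probability that a
#' co-infected cell loses its intron(-) phage lineage.
#'
#' @param params an [InterferenceParams-class].
#' @return numeric probability between 0 and 1.
#' @export
effectiveInterference <- function(params) {
  stopifnot(is(params, "InterferenceParams"))
  params@h * params@k * (1 - params@mu) * (1 - .rEff(params))
}

#' Sample per-cell adsorption counts
#'
#' Per-cell phage counts at a given multiplicity of infection are
#' Poisson(MOI), the standard adsorption assumption. Consumes the
#' current RNG stream.
#'
#' @param moi non-negative multiplicity of infection.
#' @param nCells positive number of cells.
#' @return integer vector of per-cell phage counts.
#' @examples
#' set.seed(1)
#' mean(sampleAdsorption(10, 1000) > 0) # ~ 1 - exp(-10)
#' @export
sampleAdsorption <- function(moi, nCells) {
  .assert(is.numeric(moi) && length(moi) == 1L && moi >= 0,
    "moi must be a single non-negative number")
  .assert(nCells >= 1, "nCells must be >= 1")
  rpois(as.integer(nCells), lambda = moi)
}

#' Resolve the progeny of a single infected cell
#'
#' Applies the per-cell rules: an uninfected cell yields nothing; a
#' singly infected cell yields its strain's burst; in a co-infected
#' cell strain A always bursts while strain B survives unless the
#' hybrid/escape/kill/rescue cascade eliminates it (see
#' [InterferenceParams-class]). B is only at risk when the resident A
#' strain has an active endonuclease and B's target site is intact.
#' Consumes the current RNG stream.
#'
#' @param countsA,countsB non-negative phage counts of strains A
#'   and B in the cell.
#' @param params an [InterferenceParams-class].
#' @param strains named list of two [PhageStrain-class] objects
#'   (\code{A}, \code{B}); see [defaultStrains()].
#' @return named numeric vector of progeny for \code{A} and \code{B}.
#' @examples
#' set.seed(1)
#' resolveCell(3, 1, interferenceParams(h = 1, k = 1, mu = 0))
#' @export
resolveCell <- function(countsA, countsB, params,
                        strains = defaultStrains()) {
  stopifnot(is(params, "InterferenceParams"))
  .assert(countsA >= 0 && countsB >= 0, "phage counts must be >= 0")
  burstA <- strains$A@burstSize * strains$A@replicationRate
  burstB <- strains$B@burstSize * strains$B@replicationRate
  progenyA <- if (countsA > 0) burstA else 0
  progenyB <- 0
  if (countsB > 0) {
    atRisk <- countsA > 0 && strains$A@endonucleaseActive &&
      strains$B@targetIntact
    killed <- FALSE
    if (atRisk) {
      u <- runif(4L)
      killed <- u[1L] < params@h && u[2L] >= params@mu &&
        u[3L] < params@k && u[4L] >= .rEff(params)
    }
    if (!killed) progenyB <- burstB
  }
  c(A = progenyA, B = progenyB)
}

#' Simulate one round of co-infection competition
#'
#' Aggregates the per-cell rules over \code{nCells} cells and
#' computes the intron(-) strain's fold-change relative to a
#' seed-matched control arm in which the endonuclease is inactive
#' (common random numbers: both arms share the adsorption counts and
#' per-cell event draws, which removes most Monte-Carlo variance
#' from the ratio). Strain A's progeny is identical in both arms by
#' construction, matching the observation that endonuclease deletion
#' does not change the carrier's own progeny.
#'
#' @param params an [InterferenceParams-class]; \code{seed} seeds the
#'   round.
#' @param strains named list of [PhageStrain-class] objects, see
#'   [defaultStrains()].
#' @return A [RoundResult-class].
#' @examples
#' res <- simulateRound(interferenceParams(nCells = 2e4, seed = 1))
#' foldChangeVsControl(res)
#' @export
simulateRound <- function(params, strains = defaultStrains()) {
  stopifnot(is(params, "InterferenceParams"))
  n <- params@nCells
  .assert(n >= 1L, "nCells must be >= 1")
  rEff <- .rEff(params)
  q <- params@h * params@k * (1 - params@mu) * (1 - rEff)
  burstA <- strains$A@burstSize * strains$A@replicationRate
  burstB <- strains$B@burstSize * strains$B@replicationRate

  withr::with_seed(params@seed, {
    nA <- rpois(n, params@moiA)
    nB <- rpois(n, params@moiB)
    uH <- runif(n); uMu <- runif(n); uK <- runif(n); uR <- runif(n)
  })

  co <- nA > 0L & nB > 0L
  cut <- co & uH < params@h & uMu >= params@mu & uK < params@k &
    uR >= rEff
  active <- strains$A@endonucleaseActive && strains$B@targetIntact
  killed <- if (active) cut else rep(FALSE, n)

  progenyA <- burstA * sum(nA > 0L)
  progenyBActive <- burstB * sum(nB > 0L & !killed)
  progenyBControl <- burstB * sum(nB > 0L)
  fold <- if (progenyBActive > 0) progenyBControl / progenyBActive else Inf

  new("RoundResult",
    progeny = c(A = progenyA, B = progenyBActive),
    controlProgeny = c(A = progenyA, B = progenyBControl),
    foldChange = fold,
    q = q,
    cellStats = c(
      nCells = as.numeric(n),
      nBInfected = sum(nB > 0L),
      nCoInfected = sum(co),
      nBKilled = sum(killed)
    )
  )
}

#' Monte-Carlo standard error of a simulated fold-change
#'
#' Delta-method standard error for the fold-change estimated by
#' [simulateRound()]: with \code{s} the surviving fraction of
#' infected intron(-) cells, \code{fold = 1/s} and
#' \code{SE(fold) = sqrt(s (1 - s) / nB) / s^2}.
#'
#' @param result a [RoundResult-class].
#' @return numeric standard error.
#' @export
foldChangeSE <- function(result) {
  stopifnot(is(result, "RoundResult"))
  st <- result@cellStats
  nB <- st[["nBInfected"]]
  if (nB == 0) return(NA_real_)
  s <- (nB - st[["nBKilled"]]) / nB
  if (s == 0) return(Inf)
  sqrt(s * (1 - s) / nB) / s^2
}

#' Closed-form expected fold-change of the intron(-) competitor
#'
#' The probability that an infected intron(-) cell carries no
#' intron(+) co-infection is \code{P0 = exp(-moiA)}; with effective
#' interference \code{q}, the expected fold-change of the intron(-)
#' population (endonuclease inactive over active) is
#' \deqn{F = 1 / (P0 + (1 - P0)(1 - q)).}
#' When \code{q = 1} and \code{P0 = 0} every intron(-) lineage dies
#' and \code{Inf} is returned.
#'
#' @param params an [InterferenceParams-class].
#' @return expected fold-change (>= 1), possibly \code{Inf}.
#' @examples
#' expectedFoldChange(interferenceParams(h = 0.536, k = 1, mu = 0))
#' @export
expectedFoldChange <- function(params) {
  stopifnot(is(params, "InterferenceParams"))
  q <- effectiveInterference(params)
  p0 <- exp(-params@moiA)
  denom <- p0 + (1 - p0) * (1 - q)
  if (denom == 0) return(Inf)
  1 / denom
}

#' Infer interference strength from an observed fold-change
#'
#' Exactly inverts [expectedFoldChange()]:
#' \deqn{\hat q = (1 - 1/F) / (1 - P0), \quad P0 = e^{-moiA},}
#' so that \code{expectedFoldChange} evaluated at \code{qHat}
#' returns \code{F}. When \code{h}, \code{mu} and the rescue
#' parameters are supplied (via \code{params}), the implied kill
#' probability \code{kHat = qHat / (h (1 - mu) (1 - rEff))} is also
#' reported, clipped to the unit interval with a flag when clipping occurs.
#' Interference cannot increase the competitor's titer in this
#' model, so \code{observedFold < 1} is an error.
#'
#' @param observedFold observed fold-change (>= 1).
#' @param params an [InterferenceParams-class]; \code{moiA} sets
#'   \code{P0}, and \code{h}, \code{mu}, rescue parameters are used
#'   for \code{kHat}.
#' @return list with \code{q}, \code{k}, \code{clipped} (logical:
#'   was \code{q} or \code{k} clipped to the unit interval?).
#' @examples
#' fitInterference(3.7, interferenceParams(moiA = 10))$q # ~0.7298
#' @export
fitInterference <- function(observedFold, params = interferenceParams()) {
  stopifnot(is(params, "InterferenceParams"))
  .assert(is.numeric(observedFold) && length(observedFold) == 1L &&
    observedFold >= 1,
    "observedFold must be a single number >= 1 (interference cannot increase competitor titer)")
  p0 <- exp(-params@moiA)
  qHat <- (1 - 1 / observedFold) / (1 - p0)
  clipped <- FALSE
  if (qHat > 1) {
    qHat <- 1
    clipped <- TRUE
    warning("observed fold-change exceeds the model maximum 1/P0; q clipped to 1")
  }
  denom <- params@h * (1 - params@mu) * (1 - .rEff(params))
  kHat <- if (denom > 0) qHat / denom else NA_real_
  if (!is.na(kHat) && kHat > 1) {
    kHat <- 1
    clipped <- TRUE
  }
  list(q = qHat, k = kHat, clipped = clipped)
}

#' Simulate multi-generation homing/interference dynamics
#'
#' Wright-Fisher-style phage-pool dynamics. Three genome classes are
#' tracked: the intron(+) carrier A, the intron(-) competitor Bminus
#' and Bplus, the competitor lineage after homing (intron copied in,
#' target site lost, endonuclease acquired). Each generation the
#' total MOI (\code{moiA + moiB}) is split across classes in
#' proportion to current frequencies, cells receive independent
#' Poisson counts per class, the interference cascade is applied to
#' Bminus-infected cells containing an active endonuclease carrier,
#' and the pool is rebuilt from per-cell bursts
#' (\code{burstSize * replicationRate} per surviving lineage). In
#' non-compartmentalized cells where cleavage is rescued by
#' recombination, the Bminus lineage is converted to Bplus
#' (unilateral gene conversion = homing).
#'
#' The same per-generation random draws are consumed whether or not
#' the endonuclease is active, so a run with
#' \code{endonucleaseActive = FALSE} is the exact seed-matched
#' neutral control.
#'
#' @param params an [InterferenceParams-class]; \code{generations},
#'   \code{nCells} and \code{seed} control the simulation.
#' @param strains named list of [PhageStrain-class] objects
#'   (\code{A}, \code{B}); converted Bplus genomes inherit B's
#'   replication rate and burst but carry the intron.
#' @return A [TrajectoryResult-class].
#' @examples
#' tr <- simulateTrajectory(interferenceParams(
#'   moiA = 2, moiB = 2, nCells = 2e4, generations = 10, seed = 1))
#' tail(trajectoryTable(tr))
#' @export
simulateTrajectory <- function(params, strains = defaultStrains()) {
  stopifnot(is(params, "InterferenceParams"))
  gens <- params@generations
  .assert(gens >= 1L, "generations must be >= 1")
  n <- params@nCells
  totalMoi <- params@moiA + params@moiB
  .assert(totalMoi > 0, "total MOI must be > 0")
  rEff <- .rEff(params)
  active <- strains$A@endonucleaseActive && strains$B@targetIntact
  burstA <- strains$A@burstSize * strains$A@replicationRate
  burstB <- strains$B@burstSize * strains$B@replicationRate

  freq <- c(A = params@moiA / totalMoi, Bplus = 0,
    Bminus = params@moiB / totalMoi)
  rows <- vector("list", gens + 1L)
  rows[[1L]] <- c(generation = 0, freq)

  withr::with_seed(params@seed, {
    for (g in seq_len(gens)) {
      nA <- rpois(n, totalMoi * freq[["A"]])
      nBp <- rpois(n, totalMoi * freq[["Bplus"]])
      nBm <- rpois(n, totalMoi * freq[["Bminus"]])
      uH <- runif(n); uMu <- runif(n); uK <- runif(n); uR <- runif(n)

      carrier <- nA > 0L | nBp > 0L
      atRisk <- carrier & nBm > 0L
      cutHit <- atRisk & uH < params@h & uMu >= params@mu & uK < params@k
      rescued <- cutHit & rEff > 0 & uR < rEff
      killed <- if (active) (cutHit & !rescued) else rep(FALSE, n)
      converted <- if (active) rescued else rep(FALSE, n)

      progA <- burstA * sum(nA > 0L)
      progBp <- burstB * (sum(nBp > 0L) + sum(converted))
      progBm <- burstB * sum(nBm > 0L & !killed & !converted)
      total <- progA + progBp + progBm
      if (total == 0) {
        for (gg in g:gens) rows[[gg + 1L]] <- c(generation = gg, freq)
        break
      }
      freq <- c(A = progA, Bplus = progBp, Bminus = progBm) / total
      rows[[g + 1L]] <- c(generation = g, freq)
    }
  })

  tb <- as.data.frame(do.call(rbind, rows))
  names(tb) <- c("generation", "freqA", "freqBplus", "freqBminus")
  tb$freqB <- tb$freqBplus + tb$freqBminus
  tb$intronFreq <- tb$freqA + tb$freqBplus
  new("TrajectoryResult", table = tb)
}
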