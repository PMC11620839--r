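#' Configuration for the synthetic-data generators
#'
#' A \code{SyntheticConfig} bundles every tunable of the synthetic-data
#' module: titer noise, nuclear co-import probability, capsid-count
#' distribution, the escaper substitution spectrum and the toy-genome
#' divergence. Defaults reproduce the study conditions of the wet-lab
#' assays the generators emulate: 5 replicates per titer experiment,
#' a 53.6% co-import probability over 140 nuclei, DNA-filled capsid
#' means of 22.6 (control) and 0.76 (endonuclease-treated) per
#' tomogram, an escaper spectrum dominated by substitutions of the
#' adenosine at nucleotide 3215 of the competitor's virion RNA
#' polymerase gene, and ~60% identity between the two phages' vRNAP
#' alleles.
#'
#' @slot seed integer; seed consumed by every generator.
#' @slot nReplicates positive integer; replicates per titer condition.
#' @slot titerLog10Sd non-negative; multiplicative lognormal titer noise,
#'   expressed as the standard deviation of log10(titer).
#' @slot pCoimport probability that a co-infected nucleus imports both
#'   phages' proteins (hybrid nucleus).
#' @slot nNuclei positive integer; nuclei scored per import experiment.
#' @slot capsidMeanControl,capsidMeanTreated non-negative; mean DNA-filled
#'   capsids per tomogram in each condition.
#' @slot capsidDispersion positive; negative-binomial size parameter
#'   (Poisson in the limit \code{Inf}).
#' @slot escaperSiteProbs data.frame with columns \code{position},
#'   \code{ref}, \code{alt}, \code{prob}; probabilities sum to 1.
#' @slot genomeIdentity fraction between 0 and 1; flank identity of the toy
#'   intron(+)/intron(-) gene pair.
#' @slot intronLength non-negative integer; length of the toy intron.
#'
#' @seealso [syntheticConfig()] for the user-facing constructor.
#' @export
setClass("SyntheticConfig",
  representation(
    seed = "integer",
    nReplicates = "integer",
    titerLog10Sd = "numeric",
    pCoimport = "numeric",
    nNuclei = "integer",
    capsidMeanControl = "numeric",
    capsidMeanTreated = "numeric",
    capsidDispersion = "numeric",
    escaperSiteProbs = "data.frame",
    genomeIdentity = "numeric",
    intronLength = "integer"
  )
)

setValidity("SyntheticConfig", function(object) {
  msg <- character()
  if (object@nReplicates < 1L) msg <- c(msg, "nReplicates must be >= 1")
  if (object@titerLog10Sd < 0) msg <- c(msg, "titerLog10Sd must be >= 0")
  if (object@pCoimport < 0 || object@pCoimport > 1)
    msg <- c(msg, "pCoimport must be in [0, 1]")
  if (object@nNuclei < 1L) msg <- c(msg, "nNuclei must be >= 1")
  if (object@capsidMeanControl < 0 || object@capsidMeanTreated < 0)
    msg <- c(msg, "capsid means must be >= 0")
  if (object@capsidDispersion <= 0)
    msg <- c(msg, "capsidDispersion must be > 0")
  sp <- object@escaperSiteProbs
  if (nrow(sp) == 0L) {
    msg <- c(msg, "escaperSiteProbs must be non-empty")
  } else {
    if (!all(c("position", "ref", "alt", "prob") %in% names(sp)))
      msg <- c(msg, "escaperSiteProbs needs columns position, ref, alt, prob")
    else if (abs(sum(sp$prob) - 1) > 1e-12)
      msg <- c(msg, "escaperSiteProbs$prob must sum to 1 (tolerance 1e-12)")
  }
  if (object@genomeIdentity < 0 || object@genomeIdentity > 1)
    msg <- c(msg, "genomeIdentity must be in [0, 1]")
  if (object@intronLength < 0L) msg <- c(msg, "intronLength must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Construct a SyntheticConfig
#'
#' @param seed integer seed used by all generators.
#' @param nReplicates replicates per titer condition (default 5, the
#'   design of the one-round competition experiments).
#' @param titerLog10Sd sd of log10 titer noise (default 0.2; plaque
#'   titer assay noise is not a measured quantity, see the vignette).
#' @param pCoimport hybrid-nucleus (co-import) probability, default 0.536.
#' @param nNuclei nuclei scored per import experiment, default 140.
#' @param capsidMeanControl,capsidMeanTreated mean filled capsids per
#'   tomogram, defaults 22.6 and 0.76.
#' @param capsidDispersion negative-binomial size, default 16 (calibrated
#'   to the control condition's standard error; see vignette).
#' @param escaperSiteProbs data.frame(position, ref, alt, prob); the
#'   default spectrum places 14/17 of escapes at nucleotide 3215
#'   (A>C and A>G in equal parts) and 3/17 at 3214 (G>T).
#' @param genomeIdentity flank identity of the toy gene pair, default 0.6.
#' @param intronLength toy intron length, default 300 (kept divisible by
#'   3 so the unspliced record still translates without stops).
#' @return A validated [SyntheticConfig-class] object.
#' @examples
#' cfg <- syntheticConfig(seed = 7)
#' genImportCounts(cfg)
#' @export
syntheticConfig <- function(seed = 1L,
                            nReplicates = 5L,
                            titerLog10Sd = 0.2,
                            pCoimport = 0.536,
                            nNuclei = 140L,
                            capsidMeanControl = 22.6,
                            capsidMeanTreated = 0.76,
                            capsidDispersion = 16,
                            escaperSiteProbs = defaultEscaperSpectrum(),
                            genomeIdentity = 0.6,
                            intronLength = 300L) {
  new("SyntheticConfig",
    seed = as.integer(seed),
    nReplicates = as.integer(nReplicates),
    titerLog10Sd = as.numeric(titerLog10Sd),
    pCoimport = as.numeric(pCoimport),
    nNuclei = as.integer(nNuclei),
    capsidMeanControl = as.numeric(capsidMeanControl),
    capsidMeanTreated = as.numeric(capsidMeanTreated),
    capsidDispersion = as.numeric(capsidDispersion),
    escaperSiteProbs = escaperSiteProbs,
    genomeIdentity = as.numeric(genomeIdentity),
    intronLength = as.integer(intronLength)
  )
}

#' Default escaper substitution spectrum
#'
#' Fourteen of seventeen spontaneous escapers carry a substitution of
#' the adenosine at nucleotide 3215 of the competitor vRNAP gene
#' (D1072A or D1072G at the protein level); the remaining three mutate
#' the guanine at 3214 (D1072Y). The 3215 class is split evenly
#' between the two observed alternative bases.
#'
#' @return data.frame with columns position, ref, alt, prob.
#' @export
defaultEscaperSpectrum <- function() {
  data.frame(
    position = c(3215L, 3215L, 3214L),
    ref = c("A", "A", "G"),
    alt = c("C", "G", "T"),
    prob = c(7 / 17, 7 / 17, 3 / 17),
    stringsAsFactors = FALSE
  )
}

#' A phage strain in the co-infection model
#'
#' @slot name strain identifier.
#' @slot hasIntron does the genome carry the intron (and hence the
#'   endonuclease gene)? Intron insertion destroys the target site, so
#'   \code{hasIntron} implies \code{!targetIntact}.
#' @slot endonucleaseActive is the encoded endonuclease functional?
#' @slot targetIntact does the genome carry a cleavable intron(-) site?
#' @slot replicationRate relative replication rate scaling the burst.
#' @slot burstSize mean progeny per surviving infected cell.
#' @export
setClass("PhageStrain",
  representation(
    name = "character",
    hasIntron = "logical",
    endonucleaseActive = "logical",
    targetIntact = "logical",
    replicationRate = "numeric",
    burstSize = "numeric"
  )
)

setValidity("PhageStrain", function(object) {
  msg <- character()
  if (object@hasIntron && object@targetIntact)
    msg <- c(msg, "an intron(+) allele cannot have an intact target site")
  if (object@replicationRate <= 0) msg <- c(msg, "replicationRate must be > 0")
  if (object@burstSize <= 0) msg <- c(msg, "burstSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a PhageStrain
#'
#' @param name strain identifier.
#' @param hasIntron logical; intron(+) allele carrying the endonuclease.
#' @param endonucleaseActive logical; defaults to \code{hasIntron}.
#' @param targetIntact logical; defaults to \code{!hasIntron} (insertion
#'   destroys the target site).
#' @param replicationRate relative replication rate (default 1).
#' @param burstSize mean progeny per surviving infected cell (default 30).
#' @return A [PhageStrain-class] object.
#' @examples
#' phageStrain("PhiPA3", hasIntron = TRUE)
#' @export
phageStrain <- function(name, hasIntron,
                        endonucleaseActive = hasIntron,
                        targetIntact = !hasIntron,
                        replicationRate = 1,
                        burstSize = 30) {
  new("PhageStrain",
    name = as.character(name), hasIntron = hasIntron,
    endonucleaseActive = endonucleaseActive, targetIntact = targetIntact,
    replicationRate = as.numeric(replicationRate),
    burstSize = as.numeric(burstSize)
  )
}

#' Default strain pair for the co-infection model
#'
#' Strain A is the intron(+) endonuclease carrier (the PhiPA3 role);
#' strain B is the intron(-) competitor with an intact, cleavable
#' target site (the PhiKZ role). B replicates slightly faster by
#' default, reflecting the competitor's replicative advantage.
#'
#' @param burstSize mean burst for both strains.
#' @param replicationRateB relative replication rate of strain B.
#' @return named list of two [PhageStrain-class] objects, \code{A}
#'   and \code{B}.
#' @export
defaultStrains <- function(burstSize = 30, replicationRateB = 1.2) {
  list(
    A = phageStrain("intron_plus", hasIntron = TRUE, burstSize = burstSize),
    B = phageStrain("intron_minus", hasIntron = FALSE,
      replicationRate = replicationRateB, burstSize = burstSize)
  )
}

#' Parameters of the co-infection interference model
#'
#' Collects every rate and probability of the per-cell interference
#' model. Per-cell infection counts are Poisson with the strain MOIs;
#' in a co-infected cell the intron(-) phage lineage is eliminated
#' when a hybrid nucleus forms (probability \code{h}), its target site
#' is not pre-escaped (probability \code{1 - mu}), cleavage succeeds
#' (probability \code{k}) and recombination rescue fails (probability
#' \code{1 - rEff}). Rescue is possible only without compartmental
#' separation and above a sequence-identity threshold:
#' \code{rEff = rMax} iff \code{identity >= identityThreshold} and
#' \code{!compartmentalized}, else 0.
#'
#' @slot moiA,moiB non-negative multiplicities of infection for the
#'   intron(+) (A) and intron(-) (B) strains.
#' @slot h hybrid-nucleus probability per co-infected cell.
#' @slot k cleavage kill probability given import and an intact site.
#' @slot mu heritable target-site escape probability.
#' @slot rMax recombination rescue probability at full identity.
#' @slot identity sequence identity between the two target alleles.
#' @slot identityThreshold identity below which rescue is abolished.
#' @slot compartmentalized are the genomes physically separated?
#' @slot nCells number of cells per stochastic round.
#' @slot generations generations for trajectory simulations.
#' @slot seed integer RNG seed.
#' @seealso [interferenceParams()], [simulateRound()],
#'   [expectedFoldChange()]
#' @export
setClass("InterferenceParams",
  representation(
    moiA = "numeric", moiB = "numeric",
    h = "numeric", k = "numeric", mu = "numeric",
    rMax = "numeric", identity = "numeric", identityThreshold = "numeric",
    compartmentalized = "logical",
    nCells = "integer", generations = "integer", seed = "integer"
  )
)

setValidity("InterferenceParams", function(object) {
  msg <- character()
  probs <- c(h = object@h, k = object@k, mu = object@mu, rMax = object@rMax,
    identity = object@identity, identityThreshold = object@identityThreshold)
  bad <- names(probs)[probs < 0 | probs > 1]
  if (length(bad))
    msg <- c(msg, paste0("not in [0, 1]: ", paste(bad, collapse = ", ")))
  if (object@moiA < 0 || object@moiB < 0) msg <- c(msg, "MOIs must be >= 0")
  if (object@nCells < 1L) msg <- c(msg, "nCells must be >= 1")
  if (object@generations < 1L) msg <- c(msg, "generations must be >= 1")
  if (length(msg)) msg else TRUE
})

#' Construct interference-model parameters
#'
#' Defaults are the calibration of the one-round competition
#' experiment: MOIs of 10 (intron(+)) and 0.1 (intron(-)), hybrid
#' probability \code{h = 0.536} (the measured co-import fraction),
#' certain kill (\code{k = 1}) and an escape frequency
#' \code{mu = 1.7e-5} matching the 0.0017% efficiency of plating
#' under forced endonuclease import, where escape is the only
#' survival route. \code{k} and \code{mu} are calibration choices,
#' not direct measurements. The default identity (0.6) sits below the
#' default rescue threshold (0.7), so recombination rescue is off.
#'
#' @param moiA,moiB strain MOIs.
#' @param h hybrid-nucleus probability.
#' @param k kill probability given a hybrid nucleus and intact site.
#' @param mu heritable escape probability.
#' @param rMax rescue probability at full identity.
#' @param identity target-allele identity.
#' @param identityThreshold identity below which rescue is off.
#' @param compartmentalized physical genome separation flag.
#' @param nCells cells per stochastic round.
#' @param generations trajectory length.
#' @param seed RNG seed.
#' @return A validated [InterferenceParams-class] object.
#' @examples
#' p <- interferenceParams()
#' expectedFoldChange(p)
#' @export
interferenceParams <- function(moiA = 10, moiB = 0.1,
                               h = 0.536, k = 1, mu = 1.7e-5,
                               rMax = 1, identity = 0.6,
                               identityThreshold = 0.7,
                               compartmentalized = FALSE,
                               nCells = 1e5, generations = 20L,
                               seed = 1L) {
  new("InterferenceParams",
    moiA = as.numeric(moiA), moiB = as.numeric(moiB),
    h = as.numeric(h), k = as.numeric(k), mu = as.numeric(mu),
    rMax = as.numeric(rMax), identity = as.numeric(identity),
    identityThreshold = as.numeric(identityThreshold),
    compartmentalized = compartmentalized,
    nCells = as.integer(nCells), generations = as.integer(generations),
    seed = as.integer(seed)
  )
}

#' Result of one simulated round of co-infection competition
#'
#' @slot progeny named numeric; progeny per strain (arbitrary titer
#'   units) in the active-endonuclease arm.
#' @slot controlProgeny named numeric; progeny per strain in the
#'   seed-matched endonuclease-inactive arm.
#' @slot foldChange intron(-) progeny in the control arm divided by
#'   that in the active arm.
#' @slot q effective per-co-infection interference probability
#'   \code{h * k * (1 - mu) * (1 - rEff)}.
#' @slot cellStats named numeric diagnostics (cells, infected cells,
#'   kills) used for Monte-Carlo error estimates.
#' @export
setClass("RoundResult",
  representation(
    progeny = "numeric",
    controlProgeny = "numeric",
    foldChange = "numeric",
    q = "numeric",
    cellStats = "numeric"
  )
)

setValidity("RoundResult", function(object) {
  msg <- character()
  if (any(object@progeny < 0) || any(object@controlProgeny < 0))
    msg <- c(msg, "progeny must be non-negative")
  if (object@foldChange < 0) msg <- c(msg, "foldChange must be >= 0")
  if (length(msg)) msg else TRUE
})

#' Multi-generation trajectory of strain and intron-allele frequencies
#'
#' @slot table data.frame with one row per generation (including
#'   generation 0) and columns \code{generation}, \code{freqA},
#'   \code{freqBplus}, \code{freqBminus}, \code{freqB},
#'   \code{intronFreq}. Class frequencies sum to 1 at every
#'   generation (tolerance 1e-9).
#' @export
setClass("TrajectoryResult", representation(table = "data.frame"))

setValidity("TrajectoryResult", function(object) {
  tb <- object@table
  need <- c("generation", "freqA", "freqBplus", "freqBminus",
    "freqB", "intronFreq")
  if (!all(need %in% names(tb)))
    return(paste("table must have columns", paste(need, collapse = ", ")))
  tot <- tb$freqA + tb$freqBplus + tb$freqBminus
  if (any(abs(tot - 1) > 1e-9))
    return("class frequencies must sum to 1 at every generation")
  TRUE
})

#' A synthetic 2D fluorescence image of an infected cell
#'
#' @slot intensity non-negative matrix of fluorescence values
#'   (rows = y, columns = x).
#' @slot pixelSize microns per pixel.
#' @slot mask logical matrix marking cell pixels; same dimensions as
#'   \code{intensity}.
#' @slot axis 2x2 numeric matrix; rows are the (x, y) pixel
#'   coordinates of the long-axis endpoints.
#' @export
setClass("CellImage",
  representation(
    intensity = "matrix",
    pixelSize = "numeric",
    mask = "matrix",
    axis = "matrix"
  )
)

setValidity("CellImage", function(object) {
  msg <- character()
  if (!identical(dim(object@intensity), dim(object@mask)))
    msg <- c(msg, "intensity and mask dimensions differ")
  if (!any(object@mask)) msg <- c(msg, "cell mask is empty")
  if (any(object@intensity < 0)) msg <- c(msg, "intensities must be >= 0")
  if (!identical(dim(object@axis), c(2L, 2L)))
    msg <- c(msg, "axis must be a 2x2 matrix of endpoint coordinates")
  else {
    d <- dim(object@intensity)
    x <- object@axis[, 1]; y <- object@axis[, 2]
    if (any(x < 1) || any(x > d[2]) || any(y < 1) || any(y > d[1]))
      msg <- c(msg, "axis endpoints must lie inside the image")
  }
  if (object@pixelSize <= 0) msg <- c(msg, "pixelSize must be > 0")
  if (length(msg)) msg else TRUE
})

#' Construct a CellImage
#'
#' @param intensity non-negative numeric matrix.
#' @param pixelSize microns per pixel.
#' @param mask logical matrix (defaults to all pixels).
#' @param axis 2x2 matrix of (x, y) endpoint coordinates (defaults to
#'   the horizontal mid-line).
#' @return A [CellImage-class] object.
#' @export
cellImage <- function(intensity, pixelSize = 0.05, mask = NULL, axis = NULL) {
  if (is.null(mask)) {
    mask <- matrix(TRUE, nrow(intensity), ncol(intensity))
  }
  if (is.null(axis)) {
    midY <- (nrow(intensity) + 1) / 2
    axis <- rbind(c(1, midY), c(ncol(intensity), midY))
  }
  new("CellImage", intensity = intensity, pixelSize = as.numeric(pixelSize),
    mask = mask, axis = axis)
}

#' Location of an intron within an interrupted gene
#'
#' @slot hostGene identifier of the interrupted gene.
#' @slot insertionAfter 1-based position on the interrupted gene after
#'   which the intron is inserted (0 when not detected).
#' @slot intronSequence the intervening sequence.
#' @slot detected was an insertion detected above threshold?
#' @slot score total split-alignment score.
#' @export
setClass("IntronLocus",
  representation(
    hostGene = "character",
    insertionAfter = "integer",
    intronSequence = "character",
    detected = "logical",
    score = "numeric"
  )
)

#' A mapped endonuclease target site on a competitor gene
#'
#' @slot gene competitor gene identifier.
#' @slot insertionHomologPosition 1-based competitor coordinate
#'   aligning with the intron insertion junction (the first base of
#'   the downstream exon context).
#' @slot criticalPositions nucleotide positions whose substitution
#'   confers escape (default: the two bases immediately upstream of
#'   the junction-aligned position).
#' @slot codonIndex codon number containing the critical positions.
#' @slot detected was a homologous site found above threshold?
#' @slot score total flank-alignment score.
#' @export
setClass("TargetSite",
  representation(
    gene = "character",
    insertionHomologPosition = "integer",
    criticalPositions = "integer",
    codonIndex = "integer",
    detected = "logical",
    score = "numeric"
  )
)
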