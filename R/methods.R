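#' @rdname phageHoming-accessors
#' @export
setMethod("progenyPerStrain", "RoundResult", function(object) object@progeny)

#' @rdname phageHoming-accessors
#' @export
setMethod("controlProgeny", "RoundResult",
  function(object) object@controlProgeny)

#' @rdname phageHoming-accessors
#' @export
setMethod("foldChangeVsControl", "RoundResult",
  function(object) object@foldChange)

#' @rdname phageHoming-accessors
#' @export
setMethod("interferenceQ", "RoundResult", function(object) object@q)

#' @rdname phageHoming-accessors
#' @export
setMethod("cellStats", "RoundResult", function(object) object@cellStats)

#' @rdname phageHoming-accessors
#' @export
setMethod("trajectoryTable", "TrajectoryResult", function(object) object@table)

#' @rdname phageHoming-accessors
#' @export
setMethod("intronFrequency", "TrajectoryResult",
  function(object) object@table$intronFreq)

#' @rdname phageHoming-accessors
#' @export
setMethod("strainFrequencies", "TrajectoryResult",
  function(object) object@table[, c("generation", "freqA", "freqB")])

#' @rdname phageHoming-accessors
#' @export
setMethod("intensity", "CellImage", function(object) object@intensity)

#' @rdname phageHoming-accessors
#' @export
setMethod("cellMask", "CellImage", function(object) object@mask)

#' @rdname phageHoming-accessors
#' @export
setMethod("pixelSize", "CellImage", function(object) object@pixelSize)

#' @rdname phageHoming-accessors
#' @export
setMethod("longAxis", "CellImage", function(object) object@axis)

#' @rdname phageHoming-accessors
#' @export
setMethod("insertionAfter", "IntronLocus", function(object)
  object@insertionAfter)

#' @rdname phageHoming-accessors
#' @export
setMethod("intronSequence", "IntronLocus", function(object)
  object@intronSequence)

#' @rdname phageHoming-accessors
#' @export
setMethod("insertionDetected", "IntronLocus", function(object)
  object@detected)

#' @rdname phageHoming-accessors
#' @export
setMethod("insertionDetected", "TargetSite", function(object)
  object@detected)

#' @rdname phageHoming-accessors
#' @export
setMethod("insertionAfter", "TargetSite", function(object)
  object@insertionHomologPosition)

#' @rdname phageHoming-accessors
#' @export
setMethod("criticalPositions", "TargetSite", function(object)
  object@criticalPositions)

#' @rdname phageHoming-accessors
#' @export
setMethod("codonIndex", "TargetSite", function(object) object@codonIndex)

setMethod("show", "InterferenceParams", function(object) {
  cat("InterferenceParams\n")
  cat(sprintf("  MOI A (intron+): %g   MOI B (intron-): %g\n",
    object@moiA, object@moiB))
  cat(sprintf("  h = %g, k = %g, mu = %g, rMax = %g\n",
    object@h, object@k, object@mu, object@rMax))
  cat(sprintf("  identity = %g (threshold %g), compartmentalized = %s\n",
    object@identity, object@identityThreshold, object@compartmentalized))
  cat(sprintf("  nCells = %d, generations = %d, seed = %d\n",
    object@nCells, object@generations, object@seed))
})

setMethod("show", "RoundResult", function(object) {
  cat("RoundResult (one round of co-infection competition)\n")
  cat("  progeny (endonuclease active):  ",
    paste(sprintf("%s = %.4g", names(object@progeny), object@progeny),
      collapse = ", "), "\n")
  cat("  progeny (endonuclease inactive):",
    paste(sprintf("%s = %.4g", names(object@controlProgeny),
      object@controlProgeny), collapse = ", "), "\n")
  cat(sprintf("  intron(-) fold-change vs control: %.4g  (q = %.4g)\n",
    object@foldChange, object@q))
})

setMethod("show", "TrajectoryResult", function(object) {
  tb <- object@table
  cat(sprintf("TrajectoryResult over %d generations\n", max(tb$generation)))
  cat(sprintf("  final strain frequencies: A = %.4f, B = %.4f\n",
    tb$freqA[nrow(tb)], tb$freqB[nrow(tb)]))
  cat(sprintf("  intron-allele frequency: %.4f -> %.4f\n",
    tb$intronFreq[1], tb$intronFreq[nrow(tb)]))
})

setMethod("show", "CellImage", function(object) {
  d <- dim(object@intensity)
  cat(sprintf(
    "CellImage %d x %d px (%.2f um/px), %d mask px, max intensity %.3g\n",
    d[1], d[2], object@pixelSize, sum(object@mask), max(object@intensity)))
})

setMethod("show", "IntronLocus", function(object) {
  if (!object@detected) {
    cat("IntronLocus: no insertion detected\n")
  } else {
    cat(sprintf(
      "IntronLocus in %s: intron of %d nt inserted after position %d (score %g)\n",
      object@hostGene, nchar(object@intronSequence),
      object@insertionAfter, object@score))
  }
})

setMethod("show", "TargetSite", function(object) {
  if (!object@detected) {
    cat("TargetSite: no homologous site found\n")
  } else {
    cat(sprintf(
      "TargetSite in %s: junction aligns at %d; critical positions %s (codon %d)\n",
      object@gene, object@insertionHomologPosition,
      paste(object@criticalPositions, collapse = ","), object@codonIndex))
  }
})

setMethod("show", "SyntheticConfig", function(object) {
  cat("SyntheticConfig\n")
  cat(sprintf("  seed %d, %d replicates, titer log10 sd %g\n",
    object@seed, object@nReplicates, object@titerLog10Sd))
  cat(sprintf("  co-import p = %g over %d nuclei\n",
    object@pCoimport, object@nNuclei))
  cat(sprintf("  capsid means %g (control) / %g (treated), dispersion %g\n",
    object@capsidMeanControl, object@capsidMeanTreated,
    object@capsidDispersion))
  cat(sprintf("  toy genomes: identity %g, intron %d nt\n",
    object@genomeIdentity, object@intronLength))
})
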