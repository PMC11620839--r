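#' @name phageHoming-accessors
#' @title Accessors for phageHoming S4 classes
#' @description Slot accessors for the central data containers. Slots
#'   should be reached through these functions, not with `@`.
#' @param object an S4 object from this package.
#' @return the corresponding slot value.
NULL

#' @rdname phageHoming-accessors
#' @export
setGeneric("progenyPerStrain", function(object)
  standardGeneric("progenyPerStrain"))

#' @rdname phageHoming-accessors
#' @export
setGeneric("controlProgeny", function(object)
  standardGeneric("controlProgeny"))

#' @rdname phageHoming-accessors
#' @export
setGeneric("foldChangeVsControl", function(object)
  standardGeneric("foldChangeVsControl"))

#' @rdname phageHoming-accessors
#' @export
setGeneric("interferenceQ", function(object)
  standardGeneric("interferenceQ"))

#' @rdname phageHoming-accessors
#' @export
setGeneric("cellStats", function(object) standardGeneric("cellStats"))

#' @rdname phageHoming-accessors
#' @export
setGeneric("trajectoryTable", function(object)
  standardGeneric("trajectoryTable"))

#' @rdname phageHoming-accessors
#' @export
setGeneric("intronFrequency", function(object)
  standardGeneric("intronFrequency"))

#' @rdname phageHoming-accessors
#' @export
setGeneric("strainFrequencies", function(object)
  standardGeneric("strainFrequencies"))

#' @rdname phageHoming-accessors
#' @export
setGeneric("intensity", function(object) standardGeneric("intensity"))

#' @rdname phageHoming-accessors
#' @export
setGeneric("cellMask", function(object) standardGeneric("cellMask"))

#' @rdname phageHoming-accessors
#' @export
setGeneric("pixelSize", function(object) standardGeneric("pixelSize"))

#' @rdname phageHoming-accessors
#' @export
setGeneric("longAxis", function(object) standardGeneric("longAxis"))

#' @rdname phageHoming-accessors
#' @export
setGeneric("insertionAfter", function(object)
  standardGeneric("insertionAfter"))

#' @rdname phageHoming-accessors
#' @export
setGeneric("intronSequence", function(object)
  standardGeneric("intronSequence"))

#' @rdname phageHoming-accessors
#' @export
setGeneric("insertionDetected", function(object)
  standardGeneric("insertionDetected"))

#' @rdname phageHoming-accessors
#' @export
setGeneric("criticalPositions", function(object)
  standardGeneric("criticalPositions"))

#' @rdname phageHoming-accessors
#' @export
setGeneric("codonIndex", function(object) standardGeneric("codonIndex"))
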