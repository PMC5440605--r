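#' @importClassesFrom Matrix Matrix dgCMatrix
NULL

#' Accessors for mbdDMR data classes
#'
#' Slot access for [ArraySignals-class], [CouplingMatrix-class],
#' [MethylationProfile-class] and [CpGMethylationMatrix-class] objects.
#'
#' @param x An object of the relevant class.
#' @param value Replacement value.
#' @return The slot content; replacement forms return the modified object.
#' @name accessors
NULL

#' @rdname accessors
#' @export
setGeneric("probeRanges", function(x) standardGeneric("probeRanges"))
#' @rdname accessors
#' @export
setMethod("probeRanges", "ArraySignals", function(x) x@probes)

#' @rdname accessors
#' @export
setGeneric("probeIds", function(x) standardGeneric("probeIds"))
#' @rdname accessors
#' @export
setMethod("probeIds", "ArraySignals", function(x) names(x@probes))

#' @rdname accessors
#' @export
setGeneric("signalMatrix", function(x) standardGeneric("signalMatrix"))
#' @rdname accessors
#' @export
setMethod("signalMatrix", "ArraySignals", function(x) x@signal)

#' @rdname accessors
#' @export
setGeneric("failedProbes", function(x) standardGeneric("failedProbes"))
#' @rdname accessors
#' @export
setMethod("failedProbes", "ArraySignals", function(x) x@failed)

#' @rdname accessors
#' @export
setGeneric("failedProbes<-", function(x, value) standardGeneric("failedProbes<-"))
#' @rdname accessors
#' @export
setReplaceMethod("failedProbes", "ArraySignals", function(x, value) {
  x@failed <- value
  validObject(x)
  x
})

#' @rdname accessors
#' @export
setGeneric("groundTruth", function(x) standardGeneric("groundTruth"))
#' @rdname accessors
#' @export
setMethod("groundTruth", "ArraySignals", function(x) x@truth)
#' @rdname accessors
#' @export
setMethod("groundTruth", "CpGMethylationMatrix", function(x) x@truth)

#' @rdname accessors
#' @export
setGeneric("couplingWeights", function(x) standardGeneric("couplingWeights"))
#' @rdname accessors
#' @export
setMethod("couplingWeights", "CouplingMatrix", function(x) x@weights)

#' @rdname accessors
#' @export
setGeneric("couplingRange", function(x) standardGeneric("couplingRange"))
#' @rdname accessors
#' @export
setMethod("couplingRange", "CouplingMatrix", function(x) x@dMax)

#' @rdname accessors
#' @export
setGeneric("methWindows", function(x) standardGeneric("methWindows"))
#' @rdname accessors
#' @export
setMethod("methWindows", "MethylationProfile", function(x) x@windows)

#' @rdname accessors
#' @export
setGeneric("methMean", function(x) standardGeneric("methMean"))
#' @rdname accessors
#' @export
setMethod("methMean", "MethylationProfile", function(x) x@mMean)

#' @rdname accessors
#' @export
setGeneric("methMode", function(x) standardGeneric("methMode"))
#' @rdname accessors
#' @export
setMethod("methMode", "MethylationProfile", function(x) x@mMode)

#' @rdname accessors
#' @export
setGeneric("methCI", function(x) standardGeneric("methCI"))
#' @rdname accessors
#' @export
setMethod("methCI", "MethylationProfile",
          function(x) list(lo = x@ciLo, hi = x@ciHi))

#' @rdname accessors
#' @export
setGeneric("probesUsed", function(x) standardGeneric("probesUsed"))
#' @rdname accessors
#' @export
setMethod("probesUsed", "MethylationProfile", function(x) x@nProbes)

#' @rdname accessors
#' @export
setGeneric("methValues", function(x) standardGeneric("methValues"))
#' @rdname accessors
#' @export
setMethod("methValues", "CpGMethylationMatrix", function(x) x@values)

#' @rdname accessors
#' @export
setGeneric("cpgPositions", function(x) standardGeneric("cpgPositions"))
#' @rdname accessors
#' @export
setMethod("cpgPositions", "CpGMethylationMatrix", function(x) x@cpgs)
#' @rdname accessors
#' @export
setMethod("cpgPositions", "CouplingMatrix", function(x) x@cpgs)

setMethod("show", "ArraySignals", function(object) {
  cat(sprintf("ArraySignals: %d probes x %d sample(s); %d flagged failed\n",
              length(object@probes), ncol(object@signal),
              sum(object@failed)))
})

setMethod("show", "CouplingMatrix", function(object) {
  cat(sprintf(
    "CouplingMatrix: %d probes x %d CpGs, d_max = %g nt, %d non-zero weights\n",
    nrow(object@weights), ncol(object@weights), object@dMax,
    length(object@weights@x)))
})

setMethod("show", "MethylationProfile", function(object) {
  cat(sprintf(
    "MethylationProfile: %d windows x %d sample(s); %d window(s) without usable probes\n",
    length(object@windows), ncol(object@mMean), sum(object@nProbes == 0L)))
})

setMethod("show", "CpGMethylationMatrix", function(object) {
  cat(sprintf("CpGMethylationMatrix: %d subjects x %d CpGs",
              nrow(object@values), ncol(object@values)))
  if (!is.null(object@truth)) cat(" (ground truth attached)")
  cat("\n")
})
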