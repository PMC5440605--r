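#' @import methods
#' @importFrom GenomicRanges GRanges seqnames start end width
#' @importFrom IRanges IRanges
#' @importFrom S4Vectors mcols mcols<-
NULL

setClassUnion("listOrNULL", c("list", "NULL"))

#' ArraySignals: probe-level MBD-enrichment signal
#'
#' Log2 enrichment ratios (enriched/input) for each array probe, one column
#' per hybridised sample, together with the probe coordinates and a
#' failed-probe mask. Probes whose signal hovers around a log2 ratio of 0
#' carry no enrichment information and are flagged by
#' [detectFailedProbes()].
#'
#' @slot probes [GenomicRanges::GRanges] of probe locations; names are probe
#'   identifiers.
#' @slot signal Numeric matrix, probes x samples, of log2 ratios.
#' @slot failed Logical vector, one entry per probe.
#' @slot truth Optional list of generating parameters (synthetic data only).
#' @export
setClass("ArraySignals",
  representation(
    probes = "GRanges",
    signal = "matrix",
    failed = "logical",
    truth = "listOrNULL"
  )
)

setValidity("ArraySignals", function(object) {
  msg <- character()
  np <- length(object@probes)
  if (nrow(object@signal) != np)
    msg <- c(msg, "signal matrix must have one row per probe")
  if (length(object@failed) != np)
    msg <- c(msg, "failed mask must have one entry per probe")
  ids <- names(object@probes)
  if (is.null(ids) || anyNA(ids))
    msg <- c(msg, "probes must be named by probe_id")
  else if (anyDuplicated(ids))
    msg <- c(msg, "duplicate probe_id")
  if (any(GenomicRanges::width(object@probes) < 1L))
    msg <- c(msg, "probe intervals must satisfy start < end")
  if (length(msg)) msg else TRUE
})

#' Construct an ArraySignals object
#'
#' @param probes `GRanges` of probe locations, named by probe id.
#' @param signal Numeric matrix (probes x samples) or vector of log2 ratios.
#' @param failed Logical failed-probe mask; defaults to all `FALSE`.
#' @param truth Optional list of generating parameters.
#' @return An [ArraySignals-class] object.
#' @export
ArraySignals <- function(probes, signal, failed = NULL, truth = NULL) {
  if (!is.matrix(signal)) signal <- matrix(signal, ncol = 1L)
  if (is.null(failed)) failed <- rep(FALSE, length(probes))
  new("ArraySignals", probes = probes, signal = signal,
      failed = failed, truth = truth)
}

#' CouplingMatrix: probe-to-CpG coupling weights
#'
#' Sparse weights \eqn{C_{pc} = \max(0, 1 - d/d_{max})} linking each probe's
#' signal to nearby CpGs, where \eqn{d} is the distance from the probe
#' midpoint to the CpG. Encodes the CpG-density adjustment of the
#' enrichment-signal model.
#'
#' @slot weights `Matrix::dgCMatrix`, probes x CpGs.
#' @slot dMax Coupling range in nucleotides.
#' @slot cpgs `GRanges` of the CpG positions (width-1).
#' @slot probeMid Numeric probe midpoints (0-based scale).
#' @export
setClass("CouplingMatrix",
  representation(
    weights = "Matrix",
    dMax = "numeric",
    cpgs = "GRanges",
    probeMid = "numeric"
  )
)

setValidity("CouplingMatrix", function(object) {
  msg <- character()
  if (object@dMax <= 0) msg <- c(msg, "dMax must be positive")
  if (ncol(object@weights) != length(object@cpgs))
    msg <- c(msg, "one weight column per CpG required")
  if (nrow(object@weights) != length(object@probeMid))
    msg <- c(msg, "one weight row per probe required")
  w <- object@weights@x
  if (length(w) && (min(w) < 0 || max(w) > 1))
    msg <- c(msg, "coupling weights must lie in [0, 1]")
  if (length(msg)) msg else TRUE
})

#' MethylationProfile: window-level methylation estimates
#'
#' Posterior summaries of the methylation fraction in each 100-nt window,
#' one column per sample: posterior mean and mode on [0, 1], a central 95%
#' credible interval, and the number of usable probes. Windows with no
#' usable probes are `NA`, never imputed.
#'
#' @slot windows `GRanges` tiling of the region.
#' @slot mMean,mMode,ciLo,ciHi Numeric matrices, windows x samples.
#' @slot nProbes Integer count of contributing probes per window.
#' @export
setClass("MethylationProfile",
  representation(
    windows = "GRanges",
    mMean = "matrix",
    mMode = "matrix",
    ciLo = "matrix",
    ciHi = "matrix",
    nProbes = "integer"
  )
)

setValidity("MethylationProfile", function(object) {
  msg <- character()
  nw <- length(object@windows)
  for (nm in c("mMean", "mMode", "ciLo", "ciHi")) {
    if (nrow(slot(object, nm)) != nw)
      msg <- c(msg, sprintf("%s must have one row per window", nm))
  }
  m <- object@mMean
  ok <- is.na(m) | (m >= 0 & m <= 1)
  if (!all(ok)) msg <- c(msg, "posterior means must lie in [0, 1]")
  bracket <- is.na(m) | (object@ciLo <= m + 1e-12 & object@ciHi >= m - 1e-12)
  if (!all(bracket)) msg <- c(msg, "credible interval must bracket the mean")
  if (length(object@nProbes) != nw)
    msg <- c(msg, "nProbes must have one entry per window")
  if (length(msg)) msg else TRUE
})

#' CpGMethylationMatrix: per-subject CpG methylation
#'
#' Percent methylation (0-100) per subject and CpG, as measured by
#' pyrosequencing, with strictly increasing CpG positions and, for
#' synthetic data, the generating ground truth.
#'
#' @slot values Numeric matrix, subjects x CpGs, in percent.
#' @slot cpgs `GRanges` of CpG positions (width-1), genomic order.
#' @slot truth Optional list of generating parameters.
#' @export
setClass("CpGMethylationMatrix",
  representation(
    values = "matrix",
    cpgs = "GRanges",
    truth = "listOrNULL"
  )
)

setValidity("CpGMethylationMatrix", function(object) {
  msg <- character()
  if (ncol(object@values) != length(object@cpgs))
    msg <- c(msg, "one value column per CpG required")
  v <- object@values
  if (!all(is.na(v) | (v >= 0 & v <= 100)))
    msg <- c(msg, "methylation values must lie in [0, 100]")
  p <- GenomicRanges::start(object@cpgs)
  if (length(p) > 1L && any(diff(p) <= 0))
    msg <- c(msg, "CpG positions must be strictly increasing")
  if (length(msg)) msg else TRUE
})

#' Construct a CpGMethylationMatrix
#'
#' @param values Subjects x CpGs matrix of percent methylation.
#' @param cpgs `GRanges` of CpG positions (width 1), in genomic order.
#' @param truth Optional list of generating parameters.
#' @return A [CpGMethylationMatrix-class] object.
#' @export
CpGMethylationMatrix <- function(values, cpgs, truth = NULL) {
  new("CpGMethylationMatrix", values = as.matrix(values), cpgs = cpgs,
      truth = truth)
}
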