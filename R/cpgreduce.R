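# Data reduction for correlated CpGs measured by pyrosequencing: Spearman
# correlation, contiguous clustering of adjacent CpGs, MAD dispersion
# scoring, representative selection, and harmonization of partitions
# across cohorts. Limits the number of association tests without resorting
# to genome-wide multiple-testing corrections.

methMatrixOf <- function(meth) {
  if (is(meth, "CpGMethylationMatrix")) methValues(meth) else as.matrix(meth)
}

#' Spearman correlation matrix of CpG methylation
#'
#' Pairwise complete-case Spearman rank correlation (mid-rank ties) between
#' CpG columns. A zero-variance CpG yields `NA` for its pairs.
#'
#' @param meth [CpGMethylationMatrix-class] or subjects x CpGs matrix.
#' @return Symmetric correlation matrix with unit diagonal.
#' @export
spearmanMatrix <- function(meth) {
  m <- methMatrixOf(meth)
  if (nrow(m) < 3L) stop("need at least 3 subjects")
  rho <- suppressWarnings(
    stats::cor(m, method = "spearman", use = "pairwise.complete.obs"))
  diag(rho) <- 1
  rho
}

#' Contiguous CpG clusters from adjacent correlations
#'
#' Single linkage over adjacent CpG pairs in genomic order: CpG i+1 joins
#' CpG i's block iff `rho(i, i+1) >= rhoMin`, otherwise a new block starts.
#' Clusters are therefore always contiguous runs. A missing adjacent
#' correlation forces a block boundary (with a message).
#'
#' @param corr Spearman correlation matrix (see [spearmanMatrix()]).
#' @param rhoMin Threshold in (0, 1); default 0.68, the observed
#'   within-cluster correlation floor.
#' @return Partition: list of contiguous integer index vectors.
#' @export
contiguousClusters <- function(corr, rhoMin = 0.68) {
  if (rhoMin <= 0 || rhoMin >= 1) stop("rhoMin must lie in (0, 1)")
  n <- ncol(corr)
  adj <- corr[cbind(seq_len(n - 1L), seq_len(n - 1L) + 1L)]
  if (anyNA(adj))
    message("missing adjacent correlation: block boundary forced at ",
            paste(which(is.na(adj)), collapse = ", "))
  newBlock <- is.na(adj) | adj < rhoMin
  id <- cumsum(c(TRUE, newBlock))
  unname(split(seq_len(n), id))
}

#' Median absolute deviation per CpG
#'
#' Unscaled MAD, `median(|x - median(x)|)`, complete-case per CpG. Left
#' unscaled (no 1.4826 consistency factor) because it is used only to rank
#' CpGs within a cluster.
#'
#' @inheritParams spearmanMatrix
#' @return Numeric vector of MAD scores (percent methylation units).
#' @export
madScores <- function(meth) {
  m <- methMatrixOf(meth)
  apply(m, 2L, function(x) {
    x <- x[is.finite(x)]
    if (!length(x)) stop("CpG with no observed values")
    stats::median(abs(x - stats::median(x)))
  })
}

#' Select one representative CpG per cluster
#'
#' The CpG with the highest MAD within each block represents the block in
#' downstream association tests; ties go to the lowest genomic position.
#'
#' @param partition Partition from [contiguousClusters()].
#' @param mad MAD scores from [madScores()].
#' @return Integer vector of representative CpG indices, one per block.
#' @export
selectRepresentatives <- function(partition, mad) {
  vapply(partition, function(b) {
    scores <- mad[b]
    if (all(is.na(scores))) stop("block without a defined MAD")
    b[which.max(scores)]
  }, integer(1))
}

#' Harmonize partitions across cohorts
#'
#' Finest common refinement: a block boundary appears in the output
#' wherever ANY input partition has one, so the harmonized clustering is
#' valid in every cohort. This is the meet in the partition lattice -
#' commutative, associative and idempotent.
#'
#' @param partitions List of partitions over the same CpG index set.
#' @return The refined partition (list of contiguous index vectors).
#' @export
harmonizePartitions <- function(partitions) {
  ns <- vapply(partitions, function(p) length(unlist(p)), integer(1))
  if (length(unique(ns)) != 1L) stop("partitions cover different CpG sets")
  n <- ns[1]
  for (p in partitions) {
    if (!identical(sort(unlist(p)), seq_len(n)))
      stop("each partition must cover 1..n exactly once")
  }
  # boundary after index i iff some partition ends a block at i
  boundary <- rep(FALSE, n)
  for (p in partitions)
    for (b in p) boundary[max(b)] <- TRUE
  id <- cumsum(c(TRUE, boundary[-n]))
  unname(split(seq_len(n), id))
}

#' Serialize a partition as "start-end" block strings
#' @param partition Partition (list of contiguous index vectors).
#' @return Character vector like `"1-2" "3" "4-8"`.
#' @export
formatPartition <- function(partition) {
  vapply(partition, function(b) {
    if (length(b) == 1L) as.character(b) else paste0(min(b), "-", max(b))
  }, character(1))
}
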