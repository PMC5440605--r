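# Readers/writers for the on-disk formats. Files use BED conventions
# (0-based, half-open) for coordinates and plain CSV/TSV for tables; in
# memory, coordinates live in GRanges (1-based, closed), converted at this
# boundary. Strand is ignored throughout: the analysis is strand-agnostic.

#' @importFrom utils read.delim write.table read.csv write.csv
NULL

#' Read a BED file of intervals
#'
#' 0-based half-open intervals; a strand column, if present, is ignored
#' with a note. Negative coordinates are rejected.
#'
#' @param path BED file path.
#' @return `GRanges` (unstranded, no metadata columns).
#' @export
readBed <- function(path) {
  lines <- readLines(path)
  if (!length(trimws(lines)) || all(trimws(lines) == ""))
    return(GenomicRanges::GRanges())
  gr <- rtracklayer::import(path, format = "bed")
  if (any(as.character(GenomicRanges::strand(gr)) != "*")) {
    message("strand column ignored")
    GenomicRanges::strand(gr) <- "*"
  }
  if (any(GenomicRanges::start(gr) < 1L)) stop("negative coordinates in BED")
  S4Vectors::mcols(gr) <- NULL
  gr
}

#' Write intervals as BED
#'
#' @param gr `GRanges`.
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeBed <- function(gr, path) {
  out <- gr
  S4Vectors::mcols(out) <- NULL
  GenomicRanges::strand(out) <- "*"
  rtracklayer::export(out, path, format = "bed")
  invisible(path)
}

#' Read a probe signal table
#'
#' Tab-delimited with header `probe_id, chrom, start, end` followed by one
#' or more `log2ratio` columns (one per sample; 0-based half-open
#' coordinates). Rows with `start >= end` and duplicate probe ids are
#' rejected with the offending row named.
#'
#' @param path File path.
#' @return An [ArraySignals-class] (failed mask all `FALSE`).
#' @export
readProbeTable <- function(path) {
  tab <- read.delim(path, stringsAsFactors = FALSE, check.names = FALSE)
  need <- c("probe_id", "chrom", "start", "end")
  if (!identical(names(tab)[1:4], need))
    stop("probe table must start with columns: ", paste(need, collapse = ", "))
  sigCols <- grep("^log2ratio", names(tab))
  if (!length(sigCols)) stop("no log2ratio column")
  bad <- which(!(tab$start < tab$end))
  if (length(bad)) stop("start >= end at row ", bad[1])
  if (any(tab$start < 0)) stop("negative coordinates at row ",
                               which(tab$start < 0)[1])
  dup <- which(duplicated(tab$probe_id))
  if (length(dup)) stop("duplicate probe_id at row ", dup[1])
  gr <- GenomicRanges::GRanges(tab$chrom,
    IRanges::IRanges(start = tab$start + 1L, end = tab$end))
  names(gr) <- tab$probe_id
  sig <- as.matrix(tab[, sigCols, drop = FALSE])
  colnames(sig) <- sub("^log2ratio\\.?", "", colnames(sig))
  if (ncol(sig) == 1L && colnames(sig)[1] == "") colnames(sig) <- NULL
  ArraySignals(gr, sig)
}

#' Write a probe signal table
#'
#' Inverse of [readProbeTable()]; signal values are written with 17
#' significant digits so that write-then-read round-trips exactly.
#'
#' @param signals [ArraySignals-class].
#' @param path Output path.
#' @return The path, invisibly.
#' @export
writeProbeTable <- function(signals, path) {
  gr <- probeRanges(signals)
  sig <- signalMatrix(signals)
  sigNames <- if (is.null(colnames(sig))) {
    if (ncol(sig) == 1L) "log2ratio" else paste0("log2ratio.S", seq_len(ncol(sig)))
  } else paste0("log2ratio.", colnames(sig))
  tab <- data.frame(probe_id = names(gr),
                    chrom = as.character(GenomicRanges::seqnames(gr)),
                    start = start0(gr), end = end0(gr),
                    stringsAsFactors = FALSE)
  for (j in seq_len(ncol(sig))) tab[[sigNames[j]]] <- sprintf("%.17g", sig[, j])
  write.table(tab, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read / write a CpG methylation matrix
#'
#' CSV of subjects x CpGs percent methylation (first column `subject_id`)
#' plus a BED file of the CpG positions.
#'
#' @param csvPath CSV path.
#' @param bedPath BED path of CpG positions.
#' @return A [CpGMethylationMatrix-class].
#' @export
readMethylationMatrix <- function(csvPath, bedPath) {
  tab <- read.csv(csvPath, stringsAsFactors = FALSE, check.names = FALSE)
  vals <- as.matrix(tab[, -1, drop = FALSE])
  rownames(vals) <- tab[[1]]
  CpGMethylationMatrix(vals, readBed(bedPath))
}

#' @rdname readMethylationMatrix
#' @param meth [CpGMethylationMatrix-class] to write.
#' @export
writeMethylationMatrix <- function(meth, csvPath, bedPath) {
  vals <- methValues(meth)
  tab <- data.frame(subject_id = rownames(vals), stringsAsFactors = FALSE)
  cn <- colnames(vals)
  if (is.null(cn)) cn <- paste0("cpg_", seq_len(ncol(vals)))
  for (j in seq_len(ncol(vals))) tab[[cn[j]]] <- sprintf("%.17g", vals[, j])
  write.csv(tab, csvPath, row.names = FALSE, quote = FALSE)
  writeBed(cpgPositions(meth), bedPath)
  invisible(csvPath)
}

#' Read / write a cohort table
#'
#' Plain CSV (comma, header, "." decimal, empty string = missing);
#' categorical columns (`sex`, `ethnicity`, `mode_of_delivery`, `batch`)
#' are restored as factors on read.
#'
#' @param path CSV path.
#' @return Cohort `data.frame`.
#' @export
readCohort <- function(path) {
  tab <- read.csv(path, stringsAsFactors = FALSE, na.strings = "")
  for (col in c("sex", "ethnicity", "mode_of_delivery", "batch"))
    if (col %in% names(tab)) tab[[col]] <- factor(tab[[col]])
  tab
}

#' @rdname readCohort
#' @param cohort Cohort `data.frame` to write.
#' @export
writeCohort <- function(cohort, path) {
  write.csv(cohort, path, row.names = FALSE, quote = FALSE, na = "")
  invisible(path)
}
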