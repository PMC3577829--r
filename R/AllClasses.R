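#' @useDynLib mitosalvage, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import methods
#' @importClassesFrom Biostrings QualityScaledDNAStringSet
#' @importFrom stats rnorm runif median sd
#' @importFrom utils write.table read.delim head
NULL

DNA_ALPHABET <- c("A", "C", "G", "T", "N")

MISMATCH_TYPES <- {
  b <- c("A", "C", "G", "T")
  p <- expand.grid(from = b, to = b, stringsAsFactors = FALSE)
  p <- p[p$from != p$to, ]
  paste0(p$from, ">", p$to)
}

#' Paired shotgun reads
#'
#' Holds the two mates of a paired-end library as parallel
#' [Biostrings::QualityScaledDNAStringSet] objects.  Mates are matched by
#' position; names of `mate1` identify the pair.
#'
#' @slot mate1,mate2 `QualityScaledDNAStringSet` of equal length.
#' @export
setClass("PairedReads", representation(
  mate1 = "QualityScaledDNAStringSet",
  mate2 = "QualityScaledDNAStringSet"
))

setValidity("PairedReads", function(object) {
  if (length(object@mate1) != length(object@mate2))
    return("mate1 and mate2 must have the same length")
  TRUE
})

#' @describeIn PairedReads number of pairs
#' @param x a `PairedReads` object
#' @export
setMethod("length", "PairedReads", function(x) length(x@mate1))

setMethod("show", "PairedReads", function(object) {
  cat("PairedReads with", length(object), "pairs\n")
  if (length(object) > 0)
    cat("  mate widths:", paste(range(Biostrings::width(object@mate1)),
                                collapse = "-"), "bp\n")
})

#' Construct a PairedReads object
#'
#' @param mate1,mate2 `QualityScaledDNAStringSet` objects of equal length
#'   (first and second mate of each pair, in matching order).
#' @return a [PairedReads-class] object
#' @export
PairedReads <- function(mate1, mate2) new("PairedReads", mate1 = mate1, mate2 = mate2)

#' @describeIn PairedReads first mates
#' @export
setGeneric("mate1", function(x) standardGeneric("mate1"))

#' @describeIn PairedReads second mates
#' @export
setGeneric("mate2", function(x) standardGeneric("mate2"))

#' @export
setMethod("mate1", "PairedReads", function(x) x@mate1)

#' @export
setMethod("mate2", "PairedReads", function(x) x@mate2)

#' Assembled contig with per-site pileup
#'
#' A contig as produced by [extractContigs()] and refined by [polish()]:
#' consensus bases over `{A,C,G,T,N}`, a 4 x L pileup matrix of read base
#' counts (rows `A`, `C`, `G`, `T`; filled by the polish step, zero columns
#' before it), the mean pileup depth, and a flag marking contigs whose ends
#' closed into a cycle during graph traversal.
#'
#' @slot id character contig identifier.
#' @slot consensus character consensus sequence.
#' @slot pileup integer matrix (4 x nchar(consensus)) of read base counts.
#' @slot avgCoverage mean pileup depth (0 before polishing).
#' @slot circularHint logical; `TRUE` when the contig closed into a cycle.
#' @slot kmerCoverage mean k-mer multiplicity along the contig path.
#' @export
setClass("Contig", representation(
  id = "character",
  consensus = "character",
  pileup = "matrix",
  avgCoverage = "numeric",
  circularHint = "logical",
  kmerCoverage = "numeric"
))

setValidity("Contig", function(object) {
  msg <- NULL
  if (ncol(object@pileup) > 0 &&
      ncol(object@pileup) != nchar(object@consensus))
    msg <- c(msg, "pileup must have one column per consensus base")
  if (nrow(object@pileup) > 0 && nrow(object@pileup) != 4)
    msg <- c(msg, "pileup must have 4 rows (A, C, G, T)")
  if (length(object@avgCoverage) != 1 || object@avgCoverage < 0)
    msg <- c(msg, "avgCoverage must be a single non-negative number")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn Contig constructor
#' @param id,consensus,pileup,avgCoverage,circularHint,kmerCoverage see slots
#' @export
Contig <- function(id, consensus, pileup = matrix(0L, 4, 0,
                     dimnames = list(c("A", "C", "G", "T"), NULL)),
                   avgCoverage = 0, circularHint = FALSE, kmerCoverage = 0) {
  new("Contig", id = id, consensus = consensus, pileup = pileup,
      avgCoverage = as.numeric(avgCoverage),
      circularHint = circularHint, kmerCoverage = as.numeric(kmerCoverage))
}

setMethod("show", "Contig", function(object) {
  cat("Contig", object@id, ":", nchar(object@consensus), "bp",
      if (object@circularHint) "(circular)" else "(linear)", "\n")
  cat("  average coverage:", round(object@avgCoverage, 2), "\n")
})

#' @describeIn Contig consensus sequence as a character string
#' @param x a `Contig`
#' @export
setGeneric("consensusSeq", function(x) standardGeneric("consensusSeq"))

#' @export
setMethod("consensusSeq", "Contig", function(x) x@consensus)

#' @describeIn Contig mean pileup depth
#' @export
setGeneric("avgCoverage", function(x) standardGeneric("avgCoverage"))

#' @export
setMethod("avgCoverage", "Contig", function(x) x@avgCoverage)

#' @describeIn Contig was the contig closed into a cycle?
#' @export
setGeneric("circularHint", function(x) standardGeneric("circularHint"))

#' @export
setMethod("circularHint", "Contig", function(x) x@circularHint)

#' @describeIn Contig the 4 x L pileup count matrix
#' @export
setGeneric("pileup", function(x) standardGeneric("pileup"))

#' @export
setMethod("pileup", "Contig", function(x) x@pileup)

#' @describeIn Contig contig length in bases
#' @export
setMethod("nchar", "Contig", function(x) nchar(x@consensus))

#' Directed mismatch spectrum
#'
#' Counts of the 12 directed base substitutions (consensus base to read
#' base) observed in read placements against a consensus, together with the
#' per-base opportunities (aligned columns whose consensus base is A, C, G
#' or T).  Post-mortem cytosine deamination shows up as an excess of C>T
#' and, on reads sequenced from the opposite strand, G>A.
#'
#' @slot counts named integer vector over the 12 types, e.g. `"C>T"`.
#' @slot opportunities named integer vector (`A`,`C`,`G`,`T`): aligned
#'   columns per consensus base.
#' @slot totalMismatch total mismatching bases.
#' @slot totalAligned total aligned (non-N, non-gap) bases.
#' @export
setClass("MismatchSpectrum", representation(
  counts = "numeric",
  opportunities = "numeric",
  totalMismatch = "numeric",
  totalAligned = "numeric"
))

setValidity("MismatchSpectrum", function(object) {
  msg <- NULL
  if (!identical(sort(names(object@counts)), sort(MISMATCH_TYPES)))
    msg <- c(msg, "counts must be named by the 12 directed mismatch types")
  if (!identical(sort(names(object@opportunities)), c("A", "C", "G", "T")))
    msg <- c(msg, "opportunities must be named A, C, G, T")
  if (abs(sum(object@counts) - object@totalMismatch) > 1e-8)
    msg <- c(msg, "totalMismatch must equal the sum of counts")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "MismatchSpectrum", function(object) {
  cat("MismatchSpectrum:", object@totalMismatch, "mismatches over",
      object@totalAligned, "aligned bases\n")
  r <- mismatchRates(object)
  top <- names(sort(r, decreasing = TRUE))[1:2]
  cat("  highest per-opportunity rates:", paste(top, collapse = ", "), "\n")
})

#' @describeIn MismatchSpectrum mismatch rates under either normalization:
#'   `"opportunity"` divides each count by the aligned columns whose
#'   consensus base is the source base; `"mismatch"` divides by the total
#'   mismatch count (fractions summing to 1).
#' @param x a `MismatchSpectrum`
#' @param normalize `"opportunity"` (default) or `"mismatch"`
#' @export
mismatchRates <- function(x, normalize = c("opportunity", "mismatch")) {
  normalize <- match.arg(normalize)
  cnt <- x@counts[MISMATCH_TYPES]
  if (normalize == "opportunity") {
    from <- substr(MISMATCH_TYPES, 1, 1)
    denom <- x@opportunities[from]
    r <- ifelse(denom > 0, cnt / denom, NA_real_)
  } else {
    r <- if (x@totalMismatch > 0) cnt / x@totalMismatch else cnt * 0
  }
  names(r) <- MISMATCH_TYPES
  r
}

#' @describeIn MismatchSpectrum raw counts of the 12 types
#' @export
setGeneric("mismatchCounts", function(x) standardGeneric("mismatchCounts"))

#' @export
setMethod("mismatchCounts", "MismatchSpectrum",
          function(x) x@counts[MISMATCH_TYPES])
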