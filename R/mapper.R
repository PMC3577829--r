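# Read placement under the pipeline's cost model: 2 per mismatch, 3 per
# inserted and 3 per deleted base, with acceptance thresholds on
# similarity (matches / alignment columns) and on the fraction of the
# read aligned.  Shared by assembly polishing, contamination profiling
# and damage assessment.

#' Mapping parameters
#'
#' Defaults follow the assembly/mapping-back setting: mismatch 2,
#' insertion 3, deletion 3, minimum similarity 0.97, minimum aligned read
#' fraction 0.5.  Contamination panels conventionally relax similarity to
#' 0.9 (except a human panel kept at 0.97).
#'
#' @slot mismatchCost,insertionCost,deletionCost positive integer costs.
#' @slot minSimilarity acceptance threshold on matches / alignment
#'   columns, in (0, 1].
#' @slot minLengthFraction acceptance threshold on aligned read bases /
#'   read length, in (0, 1].
#' @slot seedLength exact k-mer seed length.
#' @slot bandWidth half-width of the banded extension around the seeded
#'   diagonal, in bp.
#' @export
setClass("MapperParams", representation(
  mismatchCost = "integer", insertionCost = "integer",
  deletionCost = "integer", minSimilarity = "numeric",
  minLengthFraction = "numeric", seedLength = "integer",
  bandWidth = "integer"
))

setValidity("MapperParams", function(object) {
  msg <- NULL
  if (any(c(object@mismatchCost, object@insertionCost,
            object@deletionCost) <= 0))
    msg <- c(msg, "costs must be positive")
  if (object@minSimilarity <= 0 || object@minSimilarity > 1)
    msg <- c(msg, "minSimilarity must be in (0, 1]")
  if (object@minLengthFraction <= 0 || object@minLengthFraction > 1)
    msg <- c(msg, "minLengthFraction must be in (0, 1]")
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "MapperParams", function(object) {
  cat("MapperParams: costs ", object@mismatchCost, "/",
      object@insertionCost, "/", object@deletionCost,
      " (mismatch/ins/del), similarity >= ", object@minSimilarity,
      ", aligned fraction >= ", object@minLengthFraction, "\n", sep = "")
})

#' @describeIn MapperParams constructor
#' @param mismatchCost,insertionCost,deletionCost,minSimilarity,minLengthFraction,seedLength,bandWidth see slots
#' @export
mapperParams <- function(mismatchCost = 2L, insertionCost = 3L,
                         deletionCost = 3L, minSimilarity = 0.97,
                         minLengthFraction = 0.5, seedLength = 15L,
                         bandWidth = 15L) {
  new("MapperParams", mismatchCost = as.integer(mismatchCost),
      insertionCost = as.integer(insertionCost),
      deletionCost = as.integer(deletionCost),
      minSimilarity = minSimilarity,
      minLengthFraction = minLengthFraction,
      seedLength = as.integer(seedLength),
      bandWidth = as.integer(bandWidth))
}

.as_char_seqs <- function(x) {
  if (is(x, "PairedReads"))
    stop("expected single-end sequences; unlist pairs first", call. = FALSE)
  if (is(x, "XStringSet")) {
    s <- as.character(x)
    if (is.null(names(s))) names(s) <- paste0("seq", seq_along(s))
    return(s)
  }
  if (is.character(x)) {
    if (is.null(names(x))) names(x) <- paste0("seq", seq_along(x))
    return(toupper(x))
  }
  if (is.list(x) && all(vapply(x, is, logical(1), "Contig"))) {
    s <- vapply(x, consensusSeq, character(1))
    names(s) <- vapply(x, function(c) c@id, character(1))
    return(s)
  }
  stop("cannot interpret input as sequences", call. = FALSE)
}

#' Fitting (semiglobal) alignment of a read against a target window
#'
#' The read is aligned end to end; the target window has free end gaps.
#' The minimum-cost alignment under
#' `mismatchCost * mismatches + insertionCost * inserted_bases +
#' deletionCost * deleted_bases` is returned.  `N` never matches: it costs
#' a mismatch and is excluded from the similarity numerator.
#'
#' @param read,targetWindow character strings over `{A,C,G,T,N}`.
#' @param params a [mapperParams()] object.
#' @param band optional band half-width around `diag0`; `NULL` (default)
#'   runs the full dynamic program.  A band too narrow to admit any path
#'   is an error.
#' @param diag0 centre diagonal of the band (expected read start in the
#'   window).
#' @return one-row data.frame: `target_start`, `target_end` (0-based
#'   half-open in the window), `cost`, `matches`, `mismatches`,
#'   `insertions`, `deletions`, `similarity`, `aligned_read_fraction`,
#'   `cigar`
#' @export
alignSemiglobal <- function(read, targetWindow, params = mapperParams(),
                            band = NULL, diag0 = 0L) {
  stopifnot(nchar(read) > 0, nchar(targetWindow) > 0)
  f <- .fit_align_cpp(toupper(read), toupper(targetWindow),
                      params@mismatchCost, params@insertionCost,
                      params@deletionCost,
                      if (is.null(band)) -1L else as.integer(band),
                      as.integer(diag0))
  if (!f$ok)
    stop("band overflow: no alignment path inside the band", call. = FALSE)
  cols <- f$matches + f$mismatches + f$insertions + f$deletions
  data.frame(
    target_start = f$win_start, target_end = f$win_end, cost = f$cost,
    matches = f$matches, mismatches = f$mismatches,
    insertions = f$insertions, deletions = f$deletions,
    similarity = f$matches / cols,
    aligned_read_fraction = (f$matches + f$mismatches + f$insertions) /
      nchar(read),
    cigar = f$cigar, stringsAsFactors = FALSE)
}

#' Map reads to targets
#'
#' Seed-and-extend placement: exact k-mer seeds over both strands, banded
#' fitting extension, and the single best placement per read (more
#' matches, then lower cost, then lowest target, lowest start, plus
#' strand).  A read overhanging a target end is clipped to the
#' overlapping part, which lowers its aligned read fraction.  A placement
#' is accepted iff `aligned_read_fraction >= minLengthFraction` and
#' `similarity >= minSimilarity`; "unmapped" is a value, not an error.
#'
#' @param reads sequences to place (`DNAStringSet`,
#'   `QualityScaledDNAStringSet`, named character vector).
#' @param targets target sequences (`DNAStringSet`, named character, or a
#'   list of [Contig-class] objects).
#' @param params a [mapperParams()] object.
#' @param circular logical (recycled over targets): treat targets as
#'   circular by extending them with their first `readLength - 1` bases;
#'   reported starts stay in `[0, length)`.
#' @return data.frame with one row per read: `read_id`, `mapped`,
#'   `accepted`, `target_id`, `target_start`, `strand`, `cost`,
#'   `matches`, `mismatches`, `insertions`, `deletions`, `similarity`,
#'   `aligned_read_fraction`, `cigar`, `oriented_read`.  `target_len`
#'   attributes record the true (unextended) target lengths.
#' @export
mapReads <- function(reads, targets, params = mapperParams(),
                     circular = FALSE) {
  rs <- .as_char_seqs(reads)
  ts <- .as_char_seqs(targets)
  circular <- rep_len(circular, length(ts))
  real_len <- nchar(ts)
  maxr <- if (length(rs)) max(nchar(rs)) else 0L
  ts_ext <- ifelse(circular & real_len > 1,
                   paste0(ts, substr(ts, 1, maxr - 1)), ts)

  m <- .map_reads_cpp(unname(rs), unname(ts_ext), params@seedLength,
                      params@mismatchCost, params@insertionCost,
                      params@deletionCost, params@bandWidth, 8L)
  rl <- nchar(rs)
  cols <- m$matches + m$mismatches + m$insertions + m$deletions
  sim <- m$matches / cols
  frac <- (m$matches + m$mismatches + m$insertions) / rl
  tid <- names(ts)[m$target]
  # starts are reported in [0, target length); placements seeded in the
  # circular extension keep their unwrapped start in `tstart_ext`
  wrapped <- ifelse(is.na(m$target), NA_integer_,
                    m$tstart %% real_len[m$target])
  out <- data.frame(
    read_id = names(rs), mapped = m$found,
    accepted = !is.na(sim) & sim >= params@minSimilarity &
      frac >= params@minLengthFraction,
    target_id = tid, target_start = wrapped, tstart_ext = m$tstart,
    strand = m$strand,
    cost = m$cost, matches = m$matches, mismatches = m$mismatches,
    insertions = m$insertions, deletions = m$deletions,
    similarity = sim, aligned_read_fraction = frac,
    cigar = m$cigar, oriented_read = m$oriented,
    stringsAsFactors = FALSE)
  out$strand[!out$mapped] <- NA_character_
  attr(out, "target_len") <- stats::setNames(real_len, names(ts))
  attr(out, "circular") <- stats::setNames(circular, names(ts))
  out
}
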