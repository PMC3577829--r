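# Post-mortem damage and sequencing-error quantification: overall
# mismatch rate of raw reads against a consensus, the 12-category
# directed mismatch spectrum, a deamination-signature flag, and
# per-site allele summaries.  Mapping for damage assessment defaults to
# a permissive similarity of 0.9 so reads carrying several mismatches
# are not censored from the statistic.

#' Mapper defaults for damage assessment
#'
#' Like [mapperParams()] but with `minSimilarity = 0.9`: an acceptance
#' threshold as strict as the assembly setting (0.97) would reject 90 bp
#' reads with three or more mismatches and truncate the error-rate
#' estimator.
#'
#' @param ... overrides passed to [mapperParams()].
#' @export
damageMapperParams <- function(...) {
  args <- list(...)
  if (is.null(args$minSimilarity)) args$minSimilarity <- 0.9
  do.call(mapperParams, args)
}

#' Overall mismatch (error) rate
#'
#' Mismatching bases between raw reads and the consensus divided by the
#' aligned raw-read bases, over accepted placements.  Inserted and
#' deleted bases count in neither numerator nor denominator
#' (substitution-only statistic).  May also be called directly on the
#' two counts.
#'
#' @param x an alignment table from [mapReads()] (accepted rows are
#'   used), or a numeric mismatch count.
#' @param bases when `x` is a count: the total aligned bases.
#' @return the mismatch rate
#' @export
errorRate <- function(x, bases = NULL) {
  if (is.numeric(x)) {
    stopifnot(!is.null(bases))
    if (bases <= 0) stop("zero aligned bases", call. = FALSE)
    return(x / bases)
  }
  a <- x[x$accepted, , drop = FALSE]
  denom <- sum(a$matches + a$mismatches)
  if (denom == 0) stop("zero aligned bases", call. = FALSE)
  sum(a$mismatches) / denom
}

#' Directed mismatch spectrum
#'
#' Counts each mismatch column of the accepted placements as
#' `consensus_base > read_base`, with reads oriented onto the consensus
#' plus strand (minus-strand placements contribute their reverse
#' complement, so template-strand deamination appears as C>T and G>A).
#' Columns where either base is `N` are excluded from counts and
#' opportunities.
#'
#' @param alignments alignment table from [mapReads()] against the
#'   consensus (single target).
#' @param consensus the consensus sequence (character or `DNAStringSet`
#'   of one, or a [Contig-class]).
#' @param circular treat the consensus as circular (wrap positions).
#' @return a [MismatchSpectrum-class]
#' @export
mismatchSpectrum <- function(alignments, consensus, circular = FALSE) {
  if (is(consensus, "Contig")) {
    circular <- circularHint(consensus)
    consensus <- consensusSeq(consensus)
  }
  cons <- unname(.as_char_seqs(consensus))[1]
  a <- alignments[alignments$accepted, , drop = FALSE]
  L <- nchar(cons)
  maxr <- if (nrow(a)) max(nchar(a$oriented_read)) else 0L
  cons_ext <- if (circular) paste0(cons, substr(cons, 1L, maxr - 1L)) else cons
  res <- .accumulate_cpp(cons_ext, a$tstart_ext, a$cigar, a$oriented_read, L)
  mm <- res$mismatch
  bases <- c("A", "C", "G", "T")
  dimnames(mm) <- list(bases, bases)
  counts <- numeric(0)
  for (f in bases) for (t in bases)
    if (f != t) counts[paste0(f, ">", t)] <- mm[f, t]
  new("MismatchSpectrum",
      counts = counts[MISMATCH_TYPES],
      opportunities = stats::setNames(as.numeric(res$opportunities), bases),
      totalMismatch = res$mismatch_bases,
      totalAligned = res$aligned_bases)
}

#' Deamination signature flag
#'
#' `TRUE` iff the per-opportunity C>T and G>A rates are each at least
#' `fold` times the median of the other ten rates (a median of zero is
#' passed by any positive rate).  Diagnostics report each rate's
#' fold-over-median and whether the combined C>T + G>A share of aligned
#' bases stays below 1%, the regime where damage has little effect on
#' consensus accuracy.
#'
#' @param spectrum a [MismatchSpectrum-class].
#' @param fold threshold (default 2.5).
#' @return list: `flag`, `fold_over_median` (named 12-vector),
#'   `combined_share`, `combined_below_1pct`
#' @export
damageFlag <- function(spectrum, fold = 2.5) {
  if (any(spectrum@opportunities == 0))
    stop("zero opportunity for some consensus base", call. = FALSE)
  r <- mismatchRates(spectrum, "opportunity")
  dmg <- c("C>T", "G>A")
  med <- median(r[setdiff(MISMATCH_TYPES, dmg)])
  fom <- if (med > 0) r / med else ifelse(r > 0, Inf, 0)
  flag <- if (med > 0) all(r[dmg] >= fold * med) else all(r[dmg] > 0)
  share <- if (spectrum@totalAligned > 0)
    sum(spectrum@counts[dmg]) / spectrum@totalAligned else 0
  list(flag = flag, fold_over_median = fom, combined_share = share,
       combined_below_1pct = share < 0.01)
}

#' Allele summary over polymorphic pileup sites
#'
#' A polymorphic site is a pileup column where at least two bases have
#' count >= 1.  Reports the count of such sites and the mean, standard
#' deviation and range of the major-allele frequency across them; on a
#' homoplasmic (single-haplotype) source these frequencies sit near 1,
#' depressed only by sequencing error and damage.
#'
#' @param x a polished [Contig-class] or a 4 x L pileup count matrix.
#' @return list (`AlleleSummary`): `n_polymorphic_sites`, `mean`, `sd`,
#'   `min`, `max` (statistics `NA` when no site is polymorphic)
#' @export
alleleSummary <- function(x) {
  pu <- if (is(x, "Contig")) pileup(x) else x
  stopifnot(is.matrix(pu), nrow(pu) == 4)
  nalle <- colSums(pu >= 1)
  poly <- which(nalle >= 2)
  if (length(poly) == 0)
    return(list(n_polymorphic_sites = 0L, mean = NA_real_, sd = NA_real_,
                min = NA_real_, max = NA_real_))
  sub <- pu[, poly, drop = FALSE]
  mf <- apply(sub, 2, max) / colSums(sub)
  list(n_polymorphic_sites = length(poly), mean = mean(mf),
       sd = sd(mf), min = min(mf), max = max(mf))
}
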