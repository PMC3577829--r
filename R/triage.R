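# Coverage-based identification of the mitochondrial contig: the
# mitogenome's high cellular copy number makes its contig an extreme
# coverage outlier relative to the modal (nuclear) contig coverage.

.contig_df <- function(contigs) {
  data.frame(
    contig_id = vapply(contigs, function(x) x@id, character(1)),
    length = vapply(contigs, nchar, numeric(1)),
    avg_coverage = vapply(contigs, avgCoverage, numeric(1)),
    stringsAsFactors = FALSE)
}

#' Modal contig coverage
#'
#' Average coverages are binned at one decimal (width 0.1) and the modal
#' bin returned; ties break toward the smaller value.
#'
#' @param contigs list of [Contig-class] objects, or a numeric vector of
#'   average coverages.
#' @return the modal coverage (one decimal)
#' @export
coverageMode <- function(contigs) {
  cov <- if (is.numeric(contigs)) contigs
         else vapply(contigs, avgCoverage, numeric(1))
  if (length(cov) == 0) stop("no contigs", call. = FALSE)
  r <- round(cov, 1)
  tab <- table(r)
  vals <- as.numeric(names(tab))
  vals[tab == max(tab)][1]  # names(table) sort ascending: tie -> smaller
}

#' Identify the putative mitochondrial contig
#'
#' Candidates are contigs at least `minLength` long whose average
#' coverage is at least `minFold` times the modal contig coverage; the
#' longest candidate is flagged as the putative mitogenome.
#'
#' @param contigs list of [Contig-class] objects.
#' @param minFold coverage excess threshold (default 10).
#' @param minLength candidate length floor in bp (default 10000).
#' @return list (`TriageReport`): `n_contigs`, `coverage_mode`,
#'   `candidates` (data.frame sorted by length descending, with
#'   `fold_over_mode`), `putative_mito` (contig id or `NA`)
#' @export
identifyMito <- function(contigs, minFold = 10, minLength = 10000) {
  df <- .contig_df(contigs)
  if (nrow(df) == 0) stop("no contigs", call. = FALSE)
  mode <- coverageMode(df$avg_coverage)
  df$fold_over_mode <- df$avg_coverage / mode
  cand <- df[df$length >= minLength & df$fold_over_mode >= minFold, ,
             drop = FALSE]
  cand <- cand[order(-cand$length), , drop = FALSE]
  list(n_contigs = nrow(df), coverage_mode = mode, candidates = cand,
       putative_mito = if (nrow(cand) > 0) cand$contig_id[1] else
         NA_character_)
}

#' Expected genome-wide sequencing depth
#'
#' @param totalBases total sequenced bases retained for analysis.
#' @param genomeSize assumed haploid genome size in bp (> 0).
#' @return `totalBases / genomeSize`
#' @export
expectedDepth <- function(totalBases, genomeSize) {
  if (genomeSize <= 0) stop("genomeSize must be > 0", call. = FALSE)
  totalBases / genomeSize
}

#' Contig coverage-versus-length table
#'
#' One row per contig plus the summary shares used to characterise an
#' assembly: the fraction of contigs with depth below 5 and at or above
#' 50, and the fraction shorter than 1 kb.
#'
#' @param contigs list of [Contig-class] objects.
#' @return data.frame of contigs with attributes `frac_depth_lt5`,
#'   `frac_depth_ge50`, `frac_len_lt1kb`
#' @export
coverageLengthTable <- function(contigs) {
  df <- .contig_df(contigs)
  if (nrow(df) > 0) {
    attr(df, "frac_depth_lt5") <- mean(df$avg_coverage < 5)
    attr(df, "frac_depth_ge50") <- mean(df$avg_coverage >= 50)
    attr(df, "frac_len_lt1kb") <- mean(df$length < 1000)
  } else {
    attr(df, "frac_depth_lt5") <- NA_real_
    attr(df, "frac_depth_ge50") <- NA_real_
    attr(df, "frac_len_lt1kb") <- NA_real_
  }
  df
}
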