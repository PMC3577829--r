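# Duplicate-read removal and the read-level QC summary.

#' Remove duplicate reads
#'
#' Exact-sequence deduplication.  A single-end read is a duplicate iff its
#' base string equals that of an earlier-kept read; a pair is a duplicate
#' iff BOTH mate strings equal those of an earlier-kept pair (mate1
#' against mate1, mate2 against mate2).  The first occurrence is kept.
#' Quality strings are ignored.  With `rcAware = TRUE` a single-end read
#' also matches the reverse complement of an earlier-kept read.
#'
#' @param reads a `QualityScaledDNAStringSet` / `DNAStringSet`
#'   (single-end) or a [PairedReads-class] object.
#' @param rcAware also collapse reverse-complement identical single-end
#'   reads (off by default).
#' @return list with `kept` (same type as input) and `summary` (a
#'   [qcSummary()]-shaped data.frame; `pct_q20` is `NA` when qualities are
#'   absent)
#' @export
removeDuplicates <- function(reads, rcAware = FALSE) {
  if (is(reads, "PairedReads")) {
    key <- paste(as.character(mate1(reads)), as.character(mate2(reads)),
                 sep = "|")
    dup <- duplicated(key)
    kept <- PairedReads(mate1(reads)[!dup], mate2(reads)[!dup])
    n <- length(reads)
  } else {
    s <- as.character(reads)
    dup <- if (rcAware) {
      canon <- pmin(s, vapply(s, .revcomp_cpp, character(1),
                              USE.NAMES = FALSE))
      duplicated(canon)
    } else duplicated(s)
    kept <- reads[!dup]
    n <- length(reads)
  }
  pct <- tryCatch(qcSummary(reads)$pct_q20, error = function(e) NA_real_)
  summary <- data.frame(
    n_reads = n, pct_q20 = pct,
    n_duplicates_removed = sum(dup), n_reads_kept = n - sum(dup))
  list(kept = kept, summary = summary)
}

#' Read-level quality summary
#'
#' The QC row reported per library: read count and the percentage of base
#' calls at or above Q20 (base-call error probability <= 0.01).  The
#' percentage is computed per base call, not per read.
#'
#' @param reads a `QualityScaledDNAStringSet`, or a
#'   [PairedReads-class] (both mates pooled).
#' @return data.frame with `n_reads`, `n_bases`, `pct_q20`
#' @export
qcSummary <- function(reads) {
  if (is(reads, "PairedReads")) {
    a <- qcSummary(mate1(reads))
    b <- qcSummary(mate2(reads))
    return(data.frame(n_reads = a$n_reads,  # pairs counted once
                      n_bases = a$n_bases + b$n_bases,
                      pct_q20 = if (a$n_bases + b$n_bases == 0) 0 else
                        (a$pct_q20 * a$n_bases + b$pct_q20 * b$n_bases) /
                        (a$n_bases + b$n_bases)))
  }
  if (!is(reads, "QualityScaledXStringSet"))
    stop("qcSummary requires per-base qualities", call. = FALSE)
  if (length(reads) == 0)
    return(data.frame(n_reads = 0L, n_bases = 0L, pct_q20 = 0))
  q <- unlist(as(Biostrings::quality(reads), "IntegerList"),
              use.names = FALSE)
  tot <- length(q)
  pass <- sum(q >= 20L)
  data.frame(n_reads = length(reads), n_bases = tot,
             pct_q20 = if (tot == 0) 0 else 100 * pass / tot)
}
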