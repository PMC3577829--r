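# Metagenomic contamination profiling: non-duplicate reads are mapped
# independently against each entry of a user-supplied reference panel
# (e.g., a proxy for the target species, human, fungal and bacterial
# genome sets), each entry with its own similarity threshold.

#' Define a contamination panel entry
#'
#' @param name entry label (unique within a panel).
#' @param genomes reference sequences (`DNAStringSet`, character vector,
#'   or path to a FASTA file).
#' @param minSimilarity acceptance similarity for this entry (0.9 is the
#'   usual panel setting; 0.97 for a human panel where specificity
#'   matters).
#' @param proxy documentation flag: the entry stands in for a related
#'   taxon rather than the exact source.
#' @return a `list` usable in [profileContamination()]
#' @export
panelEntry <- function(name, genomes, minSimilarity = 0.9, proxy = FALSE) {
  if (is.character(genomes) && length(genomes) == 1 &&
      file.exists(genomes))
    genomes <- readFasta(genomes)
  stopifnot(minSimilarity > 0, minSimilarity <= 1)
  list(name = name, genomes = genomes, minSimilarity = minSimilarity,
       proxy = proxy)
}

#' Profile read composition against a reference panel
#'
#' Each read is mapped independently against each panel entry with that
#' entry's similarity threshold and a shared aligned-length fraction; a
#' read counts toward every entry it maps to, so per-entry percentages
#' may overlap.  `unidentified` is the percentage of reads mapping to no
#' entry.  With `exclusive = TRUE` each mapped read is instead assigned
#' only to the entry where it aligns with the most matches (ties to the
#' earlier panel entry), so percentages partition the reads.
#'
#' @param reads non-duplicate reads (single-end; unlist pairs first).
#' @param panel list of [panelEntry()] objects (non-empty, unique names).
#' @param lengthFraction shared minimum aligned read fraction
#'   (default 0.5).
#' @param exclusive winner-takes-best assignment instead of independent
#'   counting.
#' @return data.frame (`CompositionReport`): one row per entry plus an
#'   `unidentified` row, with `n_reads`, `pct`, `proxy`
#' @export
profileContamination <- function(reads, panel, lengthFraction = 0.5,
                                 exclusive = FALSE) {
  if (length(panel) == 0) stop("empty panel", call. = FALSE)
  nms <- vapply(panel, `[[`, "", "name")
  if (anyDuplicated(nms)) stop("panel names must be unique", call. = FALSE)
  rs <- .as_char_seqs(reads)
  n <- length(rs)
  if (n == 0) stop("no reads", call. = FALSE)

  hits <- matrix(FALSE, nrow = n, ncol = length(panel),
                 dimnames = list(NULL, nms))
  score <- matrix(-1L, nrow = n, ncol = length(panel))
  for (j in seq_along(panel)) {
    pe <- panel[[j]]
    prm <- mapperParams(minSimilarity = pe$minSimilarity,
                        minLengthFraction = lengthFraction)
    aln <- mapReads(rs, pe$genomes, params = prm)
    hits[, j] <- aln$accepted
    score[aln$accepted, j] <- aln$matches[aln$accepted]
  }

  if (exclusive) {
    assigned <- apply(score, 1, function(x)
      if (all(x < 0)) NA_integer_ else which.max(x))
    cnt <- vapply(seq_along(panel), function(j)
      sum(!is.na(assigned) & assigned == j), numeric(1))
  } else {
    cnt <- colSums(hits)
  }
  unid <- sum(rowSums(hits) == 0)

  data.frame(
    source = c(nms, "unidentified"),
    n_reads = c(cnt, unid),
    pct = 100 * c(cnt, unid) / n,
    proxy = c(vapply(panel, function(p) isTRUE(p$proxy), logical(1)), NA),
    stringsAsFactors = FALSE)
}
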