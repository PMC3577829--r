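# Sequence and report input/output.  All sequence IO goes through
# Biostrings; this layer enforces the pipeline alphabet {A,C,G,T,N}
# (uppercased on read, other IUPAC codes rejected) and fixes the quality
# encoding at Phred+33.

.check_alphabet <- function(x, where = "sequence") {
  chars <- Biostrings::uniqueLetters(x)
  bad <- setdiff(chars, DNA_ALPHABET)
  if (length(bad) > 0)
    stop(where, " contains characters outside {A,C,G,T,N}: ",
         paste(bad, collapse = ", "), call. = FALSE)
  invisible(TRUE)
}

.upper_dna <- function(x) {
  s <- toupper(as.character(x))
  bad <- grepl("[^ACGTN]", s)
  if (any(bad))
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  out <- Biostrings::DNAStringSet(s)
  names(out) <- names(x)
  out
}

#' Read a FASTQ file
#'
#' Reads Sanger-offset (Phred+33) FASTQ into a quality-scaled string set.
#' Bases are uppercased; characters outside `{A,C,G,T,N}` are an error.
#'
#' @param path path to a FASTQ file (may be gzip-compressed).
#' @return a [Biostrings::QualityScaledDNAStringSet]
#' @export
readFastq <- function(path) {
  # the Biostrings reader warns about dropping (empty) metadata columns
  # when re-binding qualities; that warning carries no information here
  muffle_mcols <- function(expr) withCallingHandlers(expr,
    warning = function(w) {
      if (grepl("metadata columns", conditionMessage(w)))
        invokeRestart("muffleWarning")
    })
  res <- tryCatch(
    muffle_mcols(Biostrings::readQualityScaledDNAStringSet(path,
      quality.scoring = "phred")),
    error = function(e) {
      n <- tryCatch(
        length(Biostrings::readBStringSet(path, format = "fastq")),
        error = function(e2) NA_integer_)
      stop("FASTQ parse error in '", path, "' near record ",
           if (is.na(n)) "?" else n + 1L, ": ", conditionMessage(e),
           call. = FALSE)
    })
  seqs <- .upper_dna(res)
  .check_alphabet(seqs, where = path)
  muffle_mcols(
    Biostrings::QualityScaledDNAStringSet(seqs, Biostrings::quality(res)))
}

#' Write reads to FASTQ (Phred+33)
#'
#' @param reads a `QualityScaledDNAStringSet` (or `DNAStringSet`, written
#'   with constant Q30 qualities).
#' @param path output path.
#' @return invisibly, `path`
#' @export
writeFastq <- function(reads, path) {
  if (!methods::is(reads, "QualityScaledXStringSet")) {
    q <- Biostrings::PhredQuality(
      vapply(Biostrings::width(reads),
             function(w) paste(rep("?", w), collapse = ""), character(1)))
    reads <- Biostrings::QualityScaledDNAStringSet(reads, q)
  }
  Biostrings::writeXStringSet(reads, path, format = "fastq",
                              qualities = Biostrings::quality(reads))
  invisible(path)
}

#' Read a FASTA file
#'
#' Sequences are uppercased on read; `U` and IUPAC ambiguity codes other
#' than `N` are rejected, keeping the whole pipeline on `{A,C,G,T,N}`.
#'
#' @param path path to a FASTA file (wrapped lines allowed).
#' @return a [Biostrings::DNAStringSet]
#' @export
readFasta <- function(path) {
  res <- Biostrings::readBStringSet(path, format = "fasta")
  s <- toupper(as.character(res))
  bad <- grepl("[^ACGTN]", s)
  if (any(bad)) {
    ch <- unique(strsplit(gsub("[ACGTN]", "", paste(s[bad], collapse = "")),
                          "")[[1]])
    stop(path, " contains characters outside {A,C,G,T,N}: ",
         paste(ch, collapse = ", "), call. = FALSE)
  }
  out <- Biostrings::DNAStringSet(s)
  names(out) <- names(res)
  out
}

#' Write sequences to FASTA
#'
#' @param seqs a `DNAStringSet`, named character vector, or `Contig` list.
#' @param path output path.
#' @param width line wrap width.
#' @return invisibly, `path`
#' @export
writeFasta <- function(seqs, path, width = 70) {
  if (is.list(seqs) && all(vapply(seqs, is, logical(1), "Contig"))) {
    s <- vapply(seqs, consensusSeq, character(1))
    names(s) <- vapply(seqs, function(x) x@id, character(1))
    seqs <- s
  }
  if (is.character(seqs)) seqs <- Biostrings::DNAStringSet(seqs)
  Biostrings::writeXStringSet(seqs, path, format = "fasta", width = width)
  invisible(path)
}

#' Reverse complement
#'
#' Reverse complement of a `{A,C,G,T,N}` string (N maps to N).  An
#' involution: `revcomp(revcomp(x)) == x`.
#'
#' @param bases a single character string, or a `DNAStringSet`.
#' @return object of the same type
#' @export
revcomp <- function(bases) {
  if (methods::is(bases, "XStringSet") || methods::is(bases, "XString")) {
    .check_alphabet(bases)
    return(Biostrings::reverseComplement(bases))
  }
  stopifnot(is.character(bases))
  bad <- grepl("[^ACGTN]", bases)
  if (any(bad))
    stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
  vapply(bases, .revcomp_cpp, character(1), USE.NAMES = FALSE)
}

#' Write a rectangular table as a TSV report
#'
#' Tab-separated, UTF-8, one header line, no quoting and no locale digit
#' grouping.  Lists of rows are checked for raggedness.
#'
#' @param table a data.frame or matrix (or list of equal-length rows).
#' @param path output path.
#' @return invisibly, `path`
#' @export
writeTsvReport <- function(table, path) {
  if (is.list(table) && !is.data.frame(table)) {
    lens <- lengths(table)
    if (length(unique(lens)) > 1)
      stop("ragged rows: lengths ", paste(unique(lens), collapse = ", "),
           call. = FALSE)
    table <- do.call(rbind, lapply(table, as.data.frame))
  }
  write.table(table, file = path, sep = "\t", quote = FALSE,
              row.names = FALSE, col.names = TRUE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Parse gene features from a GenBank flat file
#'
#' Minimal parser extracting `CDS`, `tRNA`, `rRNA`, `misc_feature` and
#' `D-loop` features: name (from `/gene`, `/product` or the feature key),
#' coordinates and strand.  Joined/multi-interval locations are reduced to
#' their outer span.  Returns the package's annotation table: 0-based
#' half-open coordinates.
#'
#' @param path path to a GenBank flat file.
#' @return data.frame with columns `region`, `start`, `end`, `strand`,
#'   `kind`
#' @export
readFeatureTable <- function(path) {
  lines <- readLines(path)
  fstart <- grep("^FEATURES", lines)
  if (length(fstart) == 0) stop("no FEATURES block in '", path, "'")
  fend <- grep("^(ORIGIN|CONTIG|//)", lines)
  fend <- if (length(fend)) min(fend[fend > fstart[1]]) else length(lines) + 1L
  block <- lines[(fstart[1] + 1L):(fend - 1L)]

  keys <- c("CDS", "tRNA", "rRNA", "misc_feature", "D-loop")
  is_feat <- grepl("^ {5}\\S", block)
  idx <- which(is_feat)
  out <- list()
  for (i in seq_along(idx)) {
    hdr <- block[idx[i]]
    key <- sub("^ +(\\S+).*$", "\\1", hdr)
    if (!key %in% keys) next
    loc <- sub("^ +\\S+ +", "", hdr)
    to <- if (i < length(idx)) idx[i + 1] - 1L else length(block)
    quals <- block[(idx[i] + 1L):to]
    # continuation lines of the location have no '/'
    cont <- quals[!grepl("/", quals)]
    if (length(cont)) loc <- paste0(loc, gsub(" ", "", paste(cont, collapse = "")))
    strand <- if (grepl("complement", loc)) "-" else "+"
    nums <- as.numeric(regmatches(loc, gregexpr("[0-9]+", loc))[[1]])
    if (length(nums) < 2) next
    gene <- grep("/gene=", quals, value = TRUE)
    prod <- grep("/product=", quals, value = TRUE)
    nm <- if (length(gene)) sub('.*"/?([^"]*)".*', "\\1",
                                sub(".*/gene=", "", gene[1]))
          else if (length(prod)) sub('.*"/?([^"]*)".*', "\\1",
                                     sub(".*/product=", "", prod[1]))
          else key
    nm <- gsub('"', "", nm)
    kind <- switch(key, CDS = "CDS", tRNA = "tRNA", rRNA = "rRNA",
                   "D-loop" = "control_region", "misc_feature")
    out[[length(out) + 1L]] <- data.frame(
      region = nm, start = min(nums) - 1L, end = max(nums),
      strand = strand, kind = kind, stringsAsFactors = FALSE)
  }
  if (length(out) == 0)
    return(data.frame(region = character(), start = integer(),
                      end = integer(), strand = character(),
                      kind = character(), stringsAsFactors = FALSE))
  do.call(rbind, out)
}
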