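# Mitogenome comparison: banded global alignment, rotation to a
# canonical start (first base of an anchor gene, conventionally
# tRNA-Phe), annotation transfer by column projection, per-region
# divergence tables, and base composition.  Nonsynonymous calls use the
# vertebrate mitochondrial genetic code.

# vertebrate mitochondrial code (differences from the standard code:
# AGA/AGG stop, ATA Met, TGA Trp)
VERT_MITO_CODE <- c(
  TTT = "F", TTC = "F", TTA = "L", TTG = "L",
  CTT = "L", CTC = "L", CTA = "L", CTG = "L",
  ATT = "I", ATC = "I", ATA = "M", ATG = "M",
  GTT = "V", GTC = "V", GTA = "V", GTG = "V",
  TCT = "S", TCC = "S", TCA = "S", TCG = "S",
  CCT = "P", CCC = "P", CCA = "P", CCG = "P",
  ACT = "T", ACC = "T", ACA = "T", ACG = "T",
  GCT = "A", GCC = "A", GCA = "A", GCG = "A",
  TAT = "Y", TAC = "Y", TAA = "*", TAG = "*",
  CAT = "H", CAC = "H", CAA = "Q", CAG = "Q",
  AAT = "N", AAC = "N", AAA = "K", AAG = "K",
  GAT = "D", GAC = "D", GAA = "E", GAG = "E",
  TGT = "C", TGC = "C", TGA = "W", TGG = "W",
  CGT = "R", CGC = "R", CGA = "R", CGG = "R",
  AGT = "S", AGC = "S", AGA = "*", AGG = "*",
  GGT = "G", GGC = "G", GGA = "G", GGG = "G")

#' Translate a codon under the vertebrate mitochondrial code
#'
#' @param codon character vector of 3-base codons over `{A,C,G,T}`.
#' @return amino-acid one-letter codes (`*` for stop, `NA` for codons
#'   containing other characters)
#' @export
translateCodonMito <- function(codon) {
  unname(VERT_MITO_CODE[toupper(codon)])
}

#' Is a codon substitution nonsynonymous?
#'
#' Classifies a single-base substitution against the frame of the first
#' (reference) codon under the vertebrate mitochondrial code.
#'
#' @param codon reference codon (3 bases).
#' @param pos substituted position within the codon (1, 2 or 3).
#' @param base replacement base.
#' @return `TRUE` if the encoded amino acid changes
#' @export
isNonsynonymous <- function(codon, pos, base) {
  alt <- codon
  substr(alt, pos, pos) <- base
  a1 <- translateCodonMito(codon)
  a2 <- translateCodonMito(alt)
  if (is.na(a1) || is.na(a2)) return(NA)
  a1 != a2
}

#' Global alignment of two mitogenome-scale sequences
#'
#' Banded global alignment under a linear gap scheme (defaults
#' match 1, mismatch -2, gap -3).  Traceback is deterministic: on ties,
#' match/mismatch is preferred over a gap in the first sequence over a
#' gap in the second.
#'
#' @param seqA,seqB sequences (character, `DNAString(Set)`).
#' @param match,mismatch,gap scores.
#' @param band band half-width around the main diagonal; `NULL` chooses
#'   `max(200, |lengths difference| + 50)`.  Sequences of very different
#'   structure may need a wider band (an error is raised if the band
#'   cannot hold the optimum path's endpoint).
#' @return list: `score`, `a`, `b` (gapped aligned strings)
#' @export
globalAlign <- function(seqA, seqB, match = 1, mismatch = -2, gap = -3,
                        band = NULL) {
  a <- unname(.as_char_seqs(seqA))[1]
  b <- unname(.as_char_seqs(seqB))[1]
  if (nchar(a) == 0 || nchar(b) == 0)
    stop("empty sequence", call. = FALSE)
  if (is.null(band))
    band <- max(200L, abs(nchar(a) - nchar(b)) + 50L)
  .global_align_cpp(a, b, as.integer(match), as.integer(mismatch),
                    as.integer(gap), as.integer(band))
}

# column maps for a gapped pairwise alignment
.aln_maps <- function(aln) {
  ac <- strsplit(aln$a, "", fixed = TRUE)[[1]]
  bc <- strsplit(aln$b, "", fixed = TRUE)[[1]]
  list(ac = ac, bc = bc,
       col_of_a = which(ac != "-"),          # a position (1-based) -> column
       apos = cumsum(ac != "-"),             # column -> last a position
       bpos = cumsum(bc != "-"))             # column -> last b position
}

#' Rotate a circular sequence to a canonical start
#'
#' Rotates (and reverse-complements if needed) a circular sequence so
#' that position 0 aligns with the first base of an anchor region
#' annotated on a reference.  The orientation with the better anchor
#' placement wins; an anchor whose best placement similarity falls
#' below `minSimilarity` is an error.
#'
#' @param circularSeq the circular sequence to rotate.
#' @param reference the annotated reference sequence.
#' @param refAnnotation annotation data.frame on the reference
#'   (`region`, `start`, `end`, `strand`, `kind`).
#' @param anchorRegion region name to anchor at (default `"tRNA-Phe"`).
#' @param minSimilarity floor on the anchor placement similarity below
#'   which the anchor is declared unalignable (default 0.7; gapped
#'   placement of a short anchor in an unrelated sequence plateaus
#'   around 0.6).
#' @return the rotated sequence (character), with attribute `offset`
#'   (rotation applied) and `flipped` (reverse-complemented first)
#' @export
rotateToStart <- function(circularSeq, reference, refAnnotation,
                          anchorRegion = "tRNA-Phe", minSimilarity = 0.7) {
  s <- unname(.as_char_seqs(circularSeq))[1]
  ref <- unname(.as_char_seqs(reference))[1]
  row <- refAnnotation[refAnnotation$region == anchorRegion, , drop = FALSE]
  if (nrow(row) == 0)
    stop("anchor region '", anchorRegion, "' not in annotation",
         call. = FALSE)
  anchor <- substr(ref, row$start[1] + 1L, row$end[1])
  if (identical(row$strand[1], "-")) anchor <- .rc1(anchor)

  L <- nchar(s)
  best <- NULL
  for (flip in c(FALSE, TRUE)) {
    t <- if (flip) .rc1(s) else s
    doubled <- paste0(t, substr(t, 1L, min(L, nchar(anchor) + 50L)))
    f <- .fit_align_cpp(anchor, doubled, 2L, 3L, 3L, -1L, 0L)
    if (!f$ok) next
    cols <- f$matches + f$mismatches + f$insertions + f$deletions
    sim <- f$matches / cols
    if (is.null(best) || f$cost < best$cost)
      best <- list(cost = f$cost, sim = sim, flip = flip,
                   offset = f$win_start %% L)
  }
  if (is.null(best) || best$sim < minSimilarity)
    stop("anchor region could not be placed on the sequence",
         call. = FALSE)
  t <- if (best$flip) .rc1(s) else s
  out <- paste0(substr(t, best$offset + 1L, L),
                substr(t, 1L, best$offset))
  attr(out, "offset") <- best$offset
  attr(out, "flipped") <- best$flip
  out
}

#' Transfer an annotation through a pairwise alignment
#'
#' Projects each region's endpoints through the alignment columns onto
#' the target; endpoints landing in target gaps are snapped inward to
#' the nearest aligned column.  Regions entirely deleted in the target
#' are flagged `missing`; transferred CDS whose length is no longer a
#' multiple of 3 are flagged `frame_disrupted`.
#'
#' @param alignment result of [globalAlign()] with the reference as
#'   `seqA` and the target as `seqB`.
#' @param refAnnotation annotation data.frame on the reference.
#' @return annotation data.frame on the target, with added `missing` and
#'   `frame_disrupted` columns
#' @export
transferAnnotation <- function(alignment, refAnnotation) {
  mp <- .aln_maps(alignment)
  ncol_aln <- length(mp$ac)
  out <- refAnnotation
  out$missing <- FALSE
  out$frame_disrupted <- FALSE
  for (i in seq_len(nrow(refAnnotation))) {
    s <- refAnnotation$start[i]; e <- refAnnotation$end[i]
    c1 <- mp$col_of_a[s + 1L]            # column of the first base
    c2 <- mp$col_of_a[e]                 # column of the last base
    # snap a start on a target gap forward, an end backward
    while (c1 <= c2 && mp$bc[c1] == "-") c1 <- c1 + 1L
    while (c2 >= c1 && mp$bc[c2] == "-") c2 <- c2 - 1L
    if (c1 > c2) {
      out$missing[i] <- TRUE
      out$start[i] <- NA_integer_; out$end[i] <- NA_integer_
      next
    }
    ts <- mp$bpos[c1] - 1L               # 0-based target start
    te <- mp$bpos[c2]                    # half-open target end
    out$start[i] <- ts; out$end[i] <- te
    if (identical(refAnnotation$kind[i], "CDS") && (te - ts) %% 3 != 0)
      out$frame_disrupted[i] <- TRUE
  }
  out
}

.region_cols <- function(mp, start, end) {
  if (end <= start) return(integer(0))
  c1 <- mp$col_of_a[start + 1L]
  c2 <- mp$col_of_a[end]
  seq.int(c1, c2)
}

#' Per-region divergence between two aligned sequences
#'
#' For each annotated region (annotation in coordinates of the first
#' sequence): alignment length in columns, segregating sites (columns
#' where both sequences carry differing unambiguous non-gap bases), gap
#' characters, columns containing `N`, and — for CDS — the nonsynonymous
#' subset of the segregating sites under the vertebrate mitochondrial
#' code, each site evaluated independently against the first sequence's
#' codon.  CDS regions whose length is not a multiple of 3 get
#' `nonsynonymous = NA`.
#'
#' @param alignment result of [globalAlign()] (first sequence carries
#'   the annotation frame).
#' @param annotation annotation data.frame on the first sequence.
#' @return data.frame of `DivergenceRow`s: `region`, `kind`,
#'   `alignment_length`, `segregating_sites`, `nonsynonymous`, `gaps`,
#'   `ambiguous`, `multi_hit_codons`
#' @export
regionDivergence <- function(alignment, annotation) {
  mp <- .aln_maps(alignment)
  rows <- lapply(seq_len(nrow(annotation)), function(i) {
    cols <- .region_cols(mp, annotation$start[i], annotation$end[i])
    a <- mp$ac[cols]; b <- mp$bc[cols]
    seg_mask <- a %in% c("A", "C", "G", "T") &
      b %in% c("A", "C", "G", "T") & a != b
    seg <- sum(seg_mask)
    gaps <- sum(a == "-") + sum(b == "-")
    amb <- sum(a == "N" | b == "N")
    nonsyn <- NA_integer_
    multi <- 0L
    if (identical(annotation$kind[i], "CDS") && length(cols) > 0) {
      apos_rel <- cumsum(a != "-")       # 1-based a position within region
      alen <- apos_rel[length(apos_rel)]
      if (alen %% 3 == 0) {
        aseq <- paste(a[a != "-"], collapse = "")
        minus <- identical(annotation$strand[i], "-")
        if (minus) aseq <- .rc1(aseq)
        seg_idx <- which(seg_mask)
        codon_of <- integer(0)
        ns <- 0L
        for (j in seg_idx) {
          p <- apos_rel[j]               # 1-based position in a's region
          base <- b[j]
          if (minus) {
            p <- alen - p + 1L
            base <- .rc1(base)
          }
          ci <- (p - 1L) %/% 3L
          off <- (p - 1L) %% 3L + 1L
          codon <- substr(aseq, ci * 3L + 1L, ci * 3L + 3L)
          hit <- isNonsynonymous(codon, off, base)
          if (isTRUE(hit)) ns <- ns + 1L
          codon_of <- c(codon_of, ci)
        }
        nonsyn <- ns
        multi <- sum(table(codon_of) > 1)
      }
    }
    data.frame(region = annotation$region[i], kind = annotation$kind[i],
               alignment_length = length(cols), segregating_sites = seg,
               nonsynonymous = nonsyn, gaps = gaps, ambiguous = amb,
               multi_hit_codons = multi, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}

#' Format a divergence table in the published cell layout
#'
#' One row per region with the alignment length and a compact
#' `segregating/nonsynonymous/gaps/ambiguous` cell (`-` where
#' nonsynonymous does not apply).
#'
#' @param div result of [regionDivergence()].
#' @return data.frame: `region`, `alignment_length`, `divergence`
#' @export
formatDivergence <- function(div) {
  cell <- sprintf("%d/%s/%d/%d", div$segregating_sites,
                  ifelse(is.na(div$nonsynonymous), "-",
                         as.character(div$nonsynonymous)),
                  div$gaps, div$ambiguous)
  data.frame(region = div$region, alignment_length = div$alignment_length,
             divergence = cell, stringsAsFactors = FALSE)
}

#' Base composition
#'
#' Fractions of G, A, T and C over unambiguous bases, with `N` counted
#' separately.
#'
#' @param sequence character, `DNAString(Set)` or [Contig-class].
#' @return list: `fractions` (named G/A/T/C), `n_count`, `length`
#' @export
composition <- function(sequence) {
  if (is(sequence, "Contig")) sequence <- consensusSeq(sequence)
  s <- unname(.as_char_seqs(sequence))[1]
  if (nchar(s) == 0) stop("empty sequence", call. = FALSE)
  ch <- strsplit(s, "", fixed = TRUE)[[1]]
  nN <- sum(ch == "N")
  unamb <- length(ch) - nN
  if (unamb == 0) stop("sequence is all N", call. = FALSE)
  fr <- vapply(c("G", "A", "T", "C"), function(b) sum(ch == b) / unamb,
               numeric(1))
  list(fractions = fr, n_count = nN, length = length(ch))
}

#' Multi-genome comparison in an anchor coordinate frame
#'
#' Aligns every genome pairwise to the first (anchor) genome, projects
#' all of them into anchor coordinates, and counts segregating sites —
#' anchor positions where all genomes carry unambiguous non-gap bases
#' and at least two differ — outside the excluded regions, together with
#' the nonsynonymous subset (any variant changing the anchor's amino
#' acid).  All-pairs per-region divergence tables computed in the same
#' frame are attached.
#'
#' @param genomes `DNAStringSet` or named character vector (>= 2; first
#'   entry is the anchor carrying the annotation frame).
#' @param annotation annotation data.frame on the anchor.
#' @param excludeRegions character vector of region names to exclude
#'   from the segregating-site count.
#' @param ... passed to [globalAlign()].
#' @return list: `segregating_sites`, `nonsynonymous`, `positions`
#'   (0-based anchor positions of the segregating sites), `pairwise`
#'   (named list of [regionDivergence()]-shaped data.frames)
#' @export
multiCompare <- function(genomes, annotation, excludeRegions = character(),
                         ...) {
  gs <- .as_char_seqs(genomes)
  if (length(gs) < 2) stop("need at least two genomes", call. = FALSE)
  anchor <- gs[[1]]
  La <- nchar(anchor)
  ng <- length(gs)

  # project every genome onto anchor positions
  proj <- matrix("-", nrow = La, ncol = ng,
                 dimnames = list(NULL, names(gs)))
  proj[, 1] <- strsplit(anchor, "", fixed = TRUE)[[1]]
  for (j in 2:ng) {
    aln <- globalAlign(anchor, gs[[j]], ...)
    mp <- .aln_maps(aln)
    acols <- mp$col_of_a
    proj[, j] <- mp$bc[acols]
  }

  excl <- rep(FALSE, La)
  if (length(excludeRegions) > 0) {
    for (i in which(annotation$region %in% excludeRegions)) {
      s <- annotation$start[i]; e <- annotation$end[i]
      excl[(s + 1L):e] <- TRUE
    }
  }

  good <- apply(proj, 1, function(x) all(x %in% c("A", "C", "G", "T")))
  vary <- apply(proj, 1, function(x) length(unique(x)) > 1)
  segpos <- which(good & vary & !excl)

  # nonsynonymous subset against the anchor codon frame
  nonsyn <- 0L
  cds <- annotation[annotation$kind == "CDS" &
                    !annotation$region %in% excludeRegions, , drop = FALSE]
  for (p in segpos) {
    row <- cds[cds$start <= (p - 1L) & cds$end >= p, , drop = FALSE]
    if (nrow(row) == 0) next
    s <- row$start[1]; e <- row$end[1]
    if ((e - s) %% 3 != 0) next
    cseq <- substr(anchor, s + 1L, e)
    minus <- identical(row$strand[1], "-")
    prel <- p - s                        # 1-based position inside CDS
    alts <- setdiff(unique(proj[p, ]), proj[p, 1])
    if (minus) {
      cseq <- .rc1(cseq)
      prel <- (e - s) - prel + 1L
      alts <- vapply(alts, .rc1, character(1), USE.NAMES = FALSE)
    }
    ci <- (prel - 1L) %/% 3L
    off <- (prel - 1L) %% 3L + 1L
    codon <- substr(cseq, ci * 3L + 1L, ci * 3L + 3L)
    if (any(vapply(alts, function(bb)
      isTRUE(isNonsynonymous(codon, off, bb)), logical(1))))
      nonsyn <- nonsyn + 1L
  }

  pairwise <- list()
  nm <- names(gs)
  for (i in seq_len(ng - 1)) for (j in (i + 1):ng) {
    # pairwise divergence in the anchor frame
    rows <- lapply(seq_len(nrow(annotation)), function(r) {
      s <- annotation$start[r]; e <- annotation$end[r]
      idx <- (s + 1L):e
      x <- proj[idx, i]; y <- proj[idx, j]
      segm <- x %in% c("A", "C", "G", "T") &
        y %in% c("A", "C", "G", "T") & x != y
      data.frame(region = annotation$region[r],
                 kind = annotation$kind[r],
                 alignment_length = length(idx),
                 segregating_sites = sum(segm),
                 nonsynonymous = NA_integer_,
                 gaps = sum(x == "-") + sum(y == "-"),
                 ambiguous = sum(x == "N" | y == "N"),
                 multi_hit_codons = 0L, stringsAsFactors = FALSE)
    })
    pairwise[[paste(nm[i], nm[j], sep = " vs ")]] <- do.call(rbind, rows)
  }

  list(segregating_sites = length(segpos), nonsynonymous = nonsyn,
       positions = segpos - 1L, pairwise = pairwise)
}
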