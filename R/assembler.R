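#' @include mapper.R
NULL

# De novo assembly: canonical k-mer de Bruijn graph, tip and bubble
# cleaning, unitig extraction, and pileup-based consensus polishing via
# the mapper.  The published knobs (mismatch/indel costs, similarity 0.97,
# overlap 0.5, contigs >= 300 bp) act at the polish/mapping-back stage;
# graph construction is governed by k and the k-mer coverage cutoff.

#' Assembly parameters
#'
#' @slot kmerSize odd k-mer size, >= 15 (default 31).
#' @slot minContigLength shortest contig reported, bp (default 300).
#' @slot minKmerCount k-mers seen fewer times are dropped from the graph
#'   (default 2), which removes most singleton sequencing-error k-mers.
#' @slot mapper [MapperParams-class] used by the polish step.
#' @export
setClass("AssemblyParams", representation(
  kmerSize = "integer", minContigLength = "integer",
  minKmerCount = "integer", mapper = "MapperParams"
))

setValidity("AssemblyParams", function(object) {
  msg <- NULL
  if (object@kmerSize < 15 || object@kmerSize %% 2 == 0)
    msg <- c(msg, "kmerSize must be odd and >= 15")
  if (object@minContigLength < object@kmerSize)
    msg <- c(msg, "minContigLength must be >= kmerSize")
  if (object@minKmerCount < 1) msg <- c(msg, "minKmerCount must be >= 1")
  if (is.null(msg)) TRUE else msg
})

#' @describeIn AssemblyParams constructor
#' @param kmerSize,minContigLength,minKmerCount,mapper see slots
#' @export
assemblyParams <- function(kmerSize = 31L, minContigLength = 300L,
                           minKmerCount = 2L, mapper = mapperParams()) {
  new("AssemblyParams", kmerSize = as.integer(kmerSize),
      minContigLength = as.integer(minContigLength),
      minKmerCount = as.integer(minKmerCount), mapper = mapper)
}

.canonical <- function(kmers) {
  if (length(kmers) == 0) return(character(0))
  rc <- as.character(Biostrings::reverseComplement(
    Biostrings::DNAStringSet(kmers)))
  pmin(kmers, rc)
}

.rc1 <- function(s) .revcomp_cpp(s)

.canon1 <- function(s) {
  r <- .revcomp_cpp(s)
  if (r < s) r else s
}

#' Build the de Bruijn graph
#'
#' Nodes are canonical k-mers (lexicographic minimum of a k-mer and its
#' reverse complement) with multiplicities; k-mers containing `N` are
#' skipped and k-mers seen fewer than `minKmerCount` times are dropped.
#'
#' @param reads sequences (`DNAStringSet`, [PairedReads-class], or
#'   character; pairs contribute both mates).
#' @param params an [assemblyParams()] object.
#' @return object of class `DeBruijnGraph`: list with `counts` (named
#'   integer vector, canonical k-mer -> multiplicity) and `k`
#' @export
buildGraph <- function(reads, params = assemblyParams()) {
  if (is(reads, "PairedReads"))
    reads <- c(as.character(mate1(reads)), as.character(mate2(reads)))
  rs <- unname(.as_char_seqs(reads))
  k <- params@kmerSize
  rs <- rs[nchar(rs) >= k]
  if (length(rs) == 0)
    stop("no read is at least kmerSize (", k, ") bases long", call. = FALSE)

  maxoff <- max(nchar(rs)) - k + 1L
  km <- vector("list", maxoff)
  for (off in seq_len(maxoff)) {
    idx <- nchar(rs) >= off + k - 1L
    km[[off]] <- substr(rs[idx], off, off + k - 1L)
  }
  km <- unlist(km, use.names = FALSE)
  km <- km[!grepl("N", km, fixed = TRUE)]
  if (length(km) == 0)
    stop("all k-mers contain N", call. = FALSE)

  r <- rle(sort(km, method = "radix"))
  canon <- .canonical(r$values)
  agg <- rowsum(r$lengths, canon)
  counts <- stats::setNames(as.integer(agg[, 1]), rownames(agg))
  counts <- counts[counts >= params@minKmerCount]
  structure(list(counts = counts, k = k), class = "DeBruijnGraph")
}

#' @export
print.DeBruijnGraph <- function(x, ...) {
  cat("DeBruijnGraph: ", length(x$counts), " canonical ", x$k,
      "-mers\n", sep = "")
  invisible(x)
}

# --- graph traversal helpers (oriented k-mer strings over an env hash) ---

.graph_env <- function(graph) {
  e <- new.env(hash = TRUE, size = max(16L, length(graph$counts)))
  nm <- names(graph$counts)
  cnt <- graph$counts
  for (i in seq_along(nm)) assign(nm[i], cnt[[i]], envir = e)
  e
}

.has_node <- function(e, oriented) {
  exists(.canon1(oriented), envir = e, inherits = FALSE)
}

.node_count <- function(e, oriented) {
  get(.canon1(oriented), envir = e, inherits = FALSE)
}

.fwd_neighbors <- function(e, oriented, k) {
  suf <- substr(oriented, 2L, k)
  cand <- paste0(suf, c("A", "C", "G", "T"))
  cand[vapply(cand, .has_node, logical(1), e = e)]
}

.bwd_neighbors <- function(e, oriented, k) {
  pre <- substr(oriented, 1L, k - 1L)
  cand <- paste0(c("A", "C", "G", "T"), pre)
  cand[vapply(cand, .has_node, logical(1), e = e)]
}

# walk forward from `start` through unique-unique extensions; returns the
# traversed sequence, the canonical k-mers visited, and whether the walk
# closed into a cycle at `start`
.walk_fwd <- function(e, start, k, visited) {
  seq_chars <- start
  canons <- .canon1(start)
  cur <- start
  circular <- FALSE
  repeat {
    nxt <- .fwd_neighbors(e, cur, k)
    if (length(nxt) != 1L) break
    if (length(.bwd_neighbors(e, nxt, k)) != 1L) break
    cn <- .canon1(nxt)
    if (cn == canons[1]) { circular <- TRUE; break }
    if (cn %in% canons) break  # sub-cycle not through start; stop
    if (exists(cn, envir = visited, inherits = FALSE)) break
    seq_chars <- c(seq_chars, substr(nxt, k, k))
    canons <- c(canons, cn)
    cur <- nxt
  }
  list(seq = paste(seq_chars, collapse = ""), canons = canons,
       circular = circular)
}

.extract_unitigs <- function(e, k) {
  keys <- sort(ls(envir = e))
  visited <- new.env(hash = TRUE, size = max(16L, length(keys)))
  unitigs <- list()
  for (km in keys) {
    if (exists(km, envir = visited, inherits = FALSE)) next
    f <- .walk_fwd(e, km, k, visited)
    if (f$circular) {
      canons <- f$canons
      seqs <- f$seq
    } else {
      b <- .walk_fwd(e, .rc1(km), k, visited)
      left <- .rc1(b$seq)
      canons <- c(rev(b$canons[-1]), f$canons)
      seqs <- paste0(substr(left, 1L, nchar(left) - k), f$seq)
    }
    for (cn in canons) assign(cn, TRUE, envir = visited)
    cov <- mean(vapply(canons, function(cn)
      get(cn, envir = e, inherits = FALSE), numeric(1)))
    first <- substr(seqs, 1L, k)
    last <- substr(seqs, nchar(seqs) - k + 1L, nchar(seqs))
    unitigs[[length(unitigs) + 1L]] <- list(
      seq = seqs, canons = canons, circular = f$circular, cov = cov,
      left_att = if (f$circular) character(0) else
        vapply(.bwd_neighbors(e, first, k), .canon1, character(1),
               USE.NAMES = FALSE),
      right_att = if (f$circular) character(0) else
        vapply(.fwd_neighbors(e, last, k), .canon1, character(1),
               USE.NAMES = FALSE))
  }
  unitigs
}

.hamming <- function(a, b) sum(charToRaw(a) != charToRaw(b))

# one cleaning pass; returns TRUE if anything was deleted
.clean_pass <- function(e, k) {
  un <- .extract_unitigs(e, k)
  if (length(un) == 0) return(FALSE)
  len <- vapply(un, function(u) nchar(u$seq), numeric(1))
  cov <- vapply(un, `[[`, 1, "cov")
  ndead <- vapply(un, function(u)
    (length(u$left_att) == 0) + (length(u$right_att) == 0), numeric(1))
  circ <- vapply(un, `[[`, TRUE, "circular")
  drop <- rep(FALSE, length(un))

  has_long <- any(len >= 2 * k)
  for (i in seq_along(un)) {
    if (circ[i] || len[i] >= 2 * k) next
    if (ndead[i] == 1) drop[i] <- TRUE                 # tip off a branch
    if (ndead[i] == 2 && has_long) drop[i] <- TRUE     # error island
  }

  # short branches far below the backbone coverage are residual error
  # paths even when they do not look like simple tips or bubbles
  ord <- order(cov)
  cum <- cumsum(len[ord])
  backbone <- cov[ord][which(cum >= sum(len) / 2)[1]]  # length-weighted median
  for (i in seq_along(un)) {
    if (circ[i] || len[i] >= 2 * k) next
    if (cov[i] < backbone / 8) drop[i] <- TRUE
  }

  # bubbles: parallel unitigs sharing both attachment sets
  key <- vapply(un, function(u) {
    a <- paste(sort(u$left_att), collapse = ",")
    b <- paste(sort(u$right_att), collapse = ",")
    paste(sort(c(a, b)), collapse = "|")
  }, character(1))
  attached <- ndead == 0 & !circ
  for (kk in unique(key[attached])) {
    grp <- which(key == kk & attached & !drop)
    if (length(grp) < 2) next
    grp <- grp[order(-vapply(un[grp], `[[`, 1, "cov"))]
    keep_seq <- .canon1(un[[grp[1]]]$seq)
    for (j in grp[-1]) {
      s <- .canon1(un[[j]]$seq)
      if (nchar(s) == nchar(keep_seq) && .hamming(s, keep_seq) <= 2)
        drop[j] <- TRUE
    }
  }

  if (!any(drop)) return(FALSE)
  for (i in which(drop))
    for (cn in un[[i]]$canons)
      if (exists(cn, envir = e, inherits = FALSE)) rm(list = cn, envir = e)
  TRUE
}

#' Extract contigs from the graph
#'
#' Tips shorter than `2k` are pruned, simple bubbles (parallel paths
#' differing by at most 2 mismatches) are collapsed onto the
#' higher-coverage branch, and maximal unambiguous paths are emitted.  A
#' path that closes into a cycle is reported once, trimmed of the
#' duplicated `(k-1)`-overlap, with `circularHint = TRUE`.  Circular
#' contigs are reported from the lexicographically minimal rotation of
#' the lexicographically smaller strand; linear contigs on their
#' lexicographically smaller strand.  Contigs shorter than
#' `minContigLength` are discarded.
#'
#' @param graph a `DeBruijnGraph` from [buildGraph()].
#' @param params an [assemblyParams()] object.
#' @return list of [Contig-class] (consensus only; pileups are added by
#'   [polish()]), sorted by decreasing length
#' @export
extractContigs <- function(graph, params = assemblyParams()) {
  k <- graph$k
  if (length(graph$counts) == 0) return(list())
  e <- .graph_env(graph)
  for (i in 1:5) if (!.clean_pass(e, k)) break
  un <- .extract_unitigs(e, k)
  if (length(un) == 0) return(list())

  seqs <- character(0); circs <- logical(0); covs <- numeric(0)
  for (u in un) {
    s <- u$seq
    if (u$circular) {
      s <- substr(s, 1L, length(u$canons))  # trim duplicated overlap
      fwd <- s; rev <- .rc1(s)
      rot <- function(x) {
        i <- .min_rotation_cpp(x)
        paste0(substr(x, i + 1L, nchar(x)), substr(x, 1L, i))
      }
      s <- min(rot(fwd), rot(rev))
    } else {
      s <- min(s, .rc1(s))
    }
    if (nchar(s) < params@minContigLength) next
    seqs <- c(seqs, s); circs <- c(circs, u$circular)
    covs <- c(covs, u$cov)
  }
  if (length(seqs) == 0) return(list())
  ord <- order(-nchar(seqs), seqs)
  lapply(seq_along(ord), function(i) {
    j <- ord[i]
    Contig(id = sprintf("contig_%d", i), consensus = seqs[j],
           circularHint = circs[j], kmerCoverage = covs[j])
  })
}

#' Polish contigs with a read pileup
#'
#' Maps every read back to the contigs (acceptance at the mapper's
#' similarity/overlap thresholds), accumulates accepted placements into
#' per-site base counts, and recalls the consensus: the plurality base
#' per column, or `N` where depth < 2 or the plurality is tied.
#'
#' @param contigs list of [Contig-class] objects.
#' @param reads the read set (pairs contribute both mates).
#' @param params an [assemblyParams()] object (`params@mapper` governs
#'   acceptance).
#' @return list of polished [Contig-class] objects, with `alignments`
#'   attribute holding the accepted-placement table
#' @export
polish <- function(contigs, reads, params = assemblyParams()) {
  if (length(contigs) == 0) stop("no contigs to polish", call. = FALSE)
  if (is(reads, "PairedReads")) {
    m1 <- as.character(mate1(reads)); m2 <- as.character(mate2(reads))
    names(m1) <- paste0(names(m1), "/1"); names(m2) <- paste0(names(m2), "/2")
    reads <- c(m1, m2)
  }
  circ <- vapply(contigs, circularHint, logical(1))
  aln <- mapReads(reads, contigs, params = params@mapper, circular = circ)
  acc <- aln[aln$accepted, , drop = FALSE]

  maxr <- if (length(reads)) max(nchar(.as_char_seqs(reads))) else 0L
  out <- lapply(contigs, function(ct) {
    L <- nchar(ct@consensus)
    a <- acc[acc$target_id == ct@id, , drop = FALSE]
    cons_ext <- if (circularHint(ct))
      paste0(ct@consensus, substr(ct@consensus, 1L, maxr - 1L))
    else ct@consensus
    res <- .accumulate_cpp(cons_ext, a$tstart_ext, a$cigar,
                           a$oriented_read, L)
    pu <- res$pileup
    rownames(pu) <- c("A", "C", "G", "T")
    depth <- colSums(pu)
    mx <- apply(pu, 2, max)
    tie <- colSums(pu == rep(mx, each = 4)) > 1 & depth > 0
    major <- rownames(pu)[apply(pu, 2, which.max)]
    newcons <- ifelse(depth < 2 | tie, "N", major)
    Contig(id = ct@id, consensus = paste(newcons, collapse = ""),
           pileup = pu, avgCoverage = mean(depth),
           circularHint = circularHint(ct),
           kmerCoverage = ct@kmerCoverage)
  })
  attr(out, "alignments") <- acc
  out
}

#' Per-site major-allele summary of a polished contig
#'
#' The coverage / major-allele-frequency track along a contig (the
#' per-base report surface of the pipeline).
#'
#' @param contig a polished [Contig-class].
#' @return data.frame: `position` (1-based), `depth`, `major_allele`,
#'   `major_freq`
#' @export
majorAlleleTrack <- function(contig) {
  pu <- pileup(contig)
  if (ncol(pu) == 0) stop("contig has no pileup; run polish() first",
                          call. = FALSE)
  depth <- colSums(pu)
  mx <- apply(pu, 2, max)
  major <- rownames(pu)[apply(pu, 2, which.max)]
  data.frame(position = seq_len(ncol(pu)), depth = depth,
             major_allele = ifelse(depth > 0, major, NA_character_),
             major_freq = ifelse(depth > 0, mx / depth, NA_real_))
}

# attempt to merge contigs bridged by read pairs; merging requires an
# exact end overlap of >= minOverlap bases (gapped scaffolding is out of
# scope)
.join_by_pairs <- function(contigs, pairs, params, minBridges = 5L,
                           minOverlap = 20L) {
  if (length(contigs) < 2) return(contigs)
  p1 <- mapReads(mate1(pairs), contigs, params = params@mapper,
                 circular = vapply(contigs, circularHint, logical(1)))
  p2 <- mapReads(mate2(pairs), contigs, params = params@mapper,
                 circular = vapply(contigs, circularHint, logical(1)))
  ok <- p1$accepted & p2$accepted & p1$target_id != p2$target_id
  if (sum(ok, na.rm = TRUE) == 0) return(contigs)
  key <- ifelse(ok & !is.na(ok),
                paste(pmin(p1$target_id, p2$target_id),
                      pmax(p1$target_id, p2$target_id)), NA)
  tab <- table(key[!is.na(key)])
  tab <- tab[tab >= minBridges]
  if (length(tab) == 0) return(contigs)

  ids <- vapply(contigs, function(x) x@id, character(1))
  merged <- rep(FALSE, length(contigs))
  out <- contigs
  for (pairkey in names(tab)) {
    ab <- strsplit(pairkey, " ")[[1]]
    ia <- match(ab[1], ids); ib <- match(ab[2], ids)
    if (merged[ia] || merged[ib]) next
    A <- consensusSeq(out[[ia]]); B <- consensusSeq(out[[ib]])
    hit <- NULL
    for (b in c(B, .rc1(B))) {
      maxov <- min(nchar(A), nchar(b)) - 1L
      if (maxov < minOverlap) next
      for (ov in seq(maxov, minOverlap)) {
        if (substr(A, nchar(A) - ov + 1L, nchar(A)) == substr(b, 1L, ov)) {
          hit <- paste0(A, substr(b, ov + 1L, nchar(b))); break
        }
        if (substr(b, nchar(b) - ov + 1L, nchar(b)) == substr(A, 1L, ov)) {
          hit <- paste0(b, substr(A, ov + 1L, nchar(A))); break
        }
      }
      if (!is.null(hit)) break
    }
    if (!is.null(hit)) {
      out[[ia]] <- Contig(id = ids[ia], consensus = hit,
                          kmerCoverage = out[[ia]]@kmerCoverage)
      merged[ib] <- TRUE
    }
  }
  out[!merged]
}

#' Assemble reads into polished contigs
#'
#' Composition of [buildGraph()], [extractContigs()] and [polish()].  In
#' paired mode, contigs bridged by at least 5 read pairs are additionally
#' joined when their ends share an exact overlap.
#'
#' @param reads a read set ([PairedReads-class] or single-end).
#' @param params an [assemblyParams()] object.
#' @param paired use read pairing to join bridged contigs; requires
#'   `reads` to be a `PairedReads`.  With `paired = FALSE` pairs are
#'   treated as independent single-end reads.
#' @return list of polished [Contig-class] objects
#' @export
assemble <- function(reads, params = assemblyParams(), paired = FALSE) {
  g <- buildGraph(reads, params)
  contigs <- extractContigs(g, params)
  if (length(contigs) == 0) return(contigs)
  if (paired) {
    if (!is(reads, "PairedReads"))
      stop("paired = TRUE requires a PairedReads object", call. = FALSE)
    contigs <- .join_by_pairs(contigs, reads, params)
  }
  polish(contigs, reads, params)
}
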