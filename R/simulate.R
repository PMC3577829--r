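# Ground-truth shotgun read simulator for degraded high-copy-number
# libraries: fragments of 200 +/- 50 bp drawn from a weighted mixture of
# (possibly circular) source genomes, sequenced as 90 bp reads with
# substitution errors, cytosine deamination on the template strand, and
# PCR duplicates that clone the final read bases.

#' Simulation configuration
#'
#' Study-condition defaults: 90 bp reads from 200 +/- 50 bp fragments
#' (normal, truncated to the +/- 50 bp window and to >= 30 bp), per-base
#' substitution error 0.004, no damage, no duplicates.  Fragment origins
#' are drawn from `sources` with probability proportional to
#' `weight * length`; circular sources wrap across the origin.
#'
#' @slot seed integer RNG seed; the single RNG stream for every stochastic
#'   step.
#' @slot nFragments number of library fragments to draw.
#' @slot readLength read length in bp.
#' @slot fragmentMean,fragmentSd fragment length distribution (bp).
#' @slot paired emit read pairs (5' read + reverse complement of the 3'
#'   end) instead of single-end reads.
#' @slot seqError per-base substitution probability.
#' @slot damageCT per-C deamination probability on the template strand
#'   (appears as G>A when the read reports the opposite strand).
#' @slot duplicateRate target fraction of duplicate-flagged reads; each
#'   fragment is re-emitted (identical final bases) with probability
#'   `duplicateRate / (1 - duplicateRate)` so the flagged fraction
#'   converges to `duplicateRate`.
#' @slot endWeighted if `TRUE`, deamination probability decays
#'   exponentially from the fragment 5' end (scale 20 bp, renormalised to
#'   keep the mean per-C rate at `damageCT`); off by default.
#' @slot lowQualFraction fraction of base calls emitted at Q10 instead of
#'   the constant Q30, for quality-summary testing.
#' @slot sources list of `list(name=, seq=, circular=, weight=)`.
#' @export
setClass("SimConfig", representation(
  seed = "integer", nFragments = "integer", readLength = "integer",
  fragmentMean = "numeric", fragmentSd = "numeric", paired = "logical",
  seqError = "numeric", damageCT = "numeric", duplicateRate = "numeric",
  endWeighted = "logical", lowQualFraction = "numeric", sources = "list"
))

setValidity("SimConfig", function(object) {
  msg <- NULL
  pr <- c(object@seqError, object@damageCT, object@duplicateRate,
          object@lowQualFraction)
  if (any(pr < 0 | pr > 1)) msg <- c(msg, "probabilities must be in [0, 1]")
  if (object@duplicateRate >= 1) msg <- c(msg, "duplicateRate must be < 1")
  if (object@readLength < 1) msg <- c(msg, "readLength must be >= 1")
  if (length(object@sources) == 0) msg <- c(msg, "at least one source required")
  for (s in object@sources) {
    if (!all(c("name", "seq", "circular", "weight") %in% names(s)))
      msg <- c(msg, "each source needs name, seq, circular, weight")
    else if (s$weight <= 0) msg <- c(msg, "source weights must be positive")
  }
  if (is.null(msg)) TRUE else msg
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig:", object@nFragments, "fragments,",
      if (object@paired) "paired" else "single-end",
      object@readLength, "bp reads\n")
  cat("  fragments ", object@fragmentMean, " +/- ", object@fragmentSd,
      " bp; seq error ", object@seqError, "; damage C>T ", object@damageCT,
      "; duplicate rate ", object@duplicateRate, "\n", sep = "")
  cat("  sources:", paste(vapply(object@sources, `[[`, "", "name"),
                          collapse = ", "), "\n")
})

#' @describeIn SimConfig constructor
#' @param seed,nFragments,readLength,fragmentMean,fragmentSd,paired,seqError,damageCT,duplicateRate,endWeighted,lowQualFraction,sources see slots
#' @export
simConfig <- function(seed, nFragments, sources, readLength = 90L,
                      fragmentMean = 200, fragmentSd = 25, paired = FALSE,
                      seqError = 0.004, damageCT = 0, duplicateRate = 0,
                      endWeighted = FALSE, lowQualFraction = 0) {
  sources <- lapply(sources, function(s) {
    s$seq <- toupper(as.character(s$seq))
    if (is.null(s$circular)) s$circular <- FALSE
    if (is.null(s$weight)) s$weight <- 1
    s
  })
  new("SimConfig", seed = as.integer(seed),
      nFragments = as.integer(nFragments),
      readLength = as.integer(readLength), fragmentMean = fragmentMean,
      fragmentSd = fragmentSd, paired = paired, seqError = seqError,
      damageCT = damageCT, duplicateRate = duplicateRate,
      endWeighted = endWeighted, lowQualFraction = lowQualFraction,
      sources = sources)
}

#' Simulate a uniform-random genome
#'
#' @param length genome length in bp (>= 1).
#' @param seed RNG seed; the same seed always yields the same sequence.
#' @param circular stored in the name metadata only; circularity is a
#'   property the simulator and assembler act on, not the sequence itself.
#' @return a single-entry [Biostrings::DNAStringSet]
#' @export
simulateGenome <- function(length, seed, circular = FALSE) {
  if (length < 1) stop("genome length must be >= 1", call. = FALSE)
  set.seed(seed)
  s <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
             collapse = "")
  out <- Biostrings::DNAStringSet(s)
  names(out) <- sprintf("sim_genome_len%d_seed%d%s", length, seed,
                        if (circular) "_circular" else "")
  out
}

.mutate_fragment <- function(chars, damage_p, seq_error, end_weighted) {
  n_damage <- 0L
  if (damage_p > 0) {
    cpos <- which(chars == "C")
    if (length(cpos) > 0) {
      p <- if (end_weighted) {
        w <- exp(-(cpos - 1) / 20)
        pmin(1, damage_p * w / mean(exp(-(seq_along(chars) - 1) / 20)))
      } else damage_p
      hit <- runif(length(cpos)) < p
      chars[cpos[hit]] <- "T"
      n_damage <- sum(hit)
    }
  }
  n_err <- 0L
  if (seq_error > 0) {
    epos <- which(runif(length(chars)) < seq_error)
    if (length(epos) > 0) {
      for (p in epos) {
        alt <- setdiff(c("A", "C", "G", "T"), chars[p])
        chars[p] <- alt[sample.int(3L, 1L)]
      }
      n_err <- length(epos)
    }
  }
  list(chars = chars, n_damage = n_damage, n_err = n_err,
       # event positions are not tracked individually; counts suffice
       NULL)
}

#' Simulate shotgun reads with ground truth
#'
#' Draws fragments from the configured sources, applies deamination on the
#' template strand first and sequencing error second, and emits single-end
#' reads (the fragment 5' end) or pairs (5' end plus the reverse
#' complement of the 3' end), each clipped to the read length.  Duplicates
#' clone the final (post-error) read bases.
#'
#' @param config a [SimConfig-class] object.
#' @return list with elements `reads` (a `QualityScaledDNAStringSet`, or a
#'   [PairedReads-class] in paired mode) and `truth` (data.frame with
#'   `read_id`, `source_name`, `source_start` (0-based on the source plus
#'   strand), `strand`, `frag_len`, `n_seq_errors`, `n_damage_events`,
#'   `is_duplicate`)
#' @export
simulateReads <- function(config) {
  stopifnot(is(config, "SimConfig"))
  validObject(config)
  set.seed(config@seed)

  srcs <- config@sources
  nm <- vapply(srcs, `[[`, "", "name")
  seqs <- vapply(srcs, `[[`, "", "seq")
  circ <- vapply(srcs, `[[`, TRUE, "circular")
  wt <- vapply(srcs, `[[`, 1, "weight")
  L <- nchar(seqs)
  rl <- config@readLength

  n <- config@nFragments
  src_i <- sample.int(length(srcs), n, replace = TRUE, prob = wt * L)

  # truncated-normal fragment lengths, then floor at 30 bp and source size
  lo <- config@fragmentMean - 50
  hi <- config@fragmentMean + 50
  flen <- rnorm(n, config@fragmentMean, config@fragmentSd)
  bad <- which(flen < lo | flen > hi)
  while (length(bad) > 0) {
    flen[bad] <- rnorm(length(bad), config@fragmentMean, config@fragmentSd)
    bad <- bad[flen[bad] < lo | flen[bad] > hi]
  }
  flen <- pmax(30L, as.integer(round(flen)))
  flen <- pmin(flen, L[src_i])

  start <- integer(n)
  for (k in seq_along(srcs)) {
    i <- which(src_i == k)
    if (length(i) == 0) next
    start[i] <- if (circ[k]) {
      as.integer(floor(runif(length(i), 0, L[k])))
    } else {
      as.integer(floor(runif(length(i), 0, L[k] - flen[i] + 1)))
    }
  }
  strand <- sample(c("+", "-"), n, replace = TRUE)

  # doubled sequence gives wrap-around extraction for circular sources
  ext <- ifelse(circ, paste0(seqs, substr(seqs, 1, hi + 1)), seqs)
  frag_plus <- substring(ext[src_i], start + 1L, start + flen)

  template <- frag_plus
  minus <- strand == "-"
  if (any(minus))
    template[minus] <- vapply(template[minus], .revcomp_cpp, character(1),
                              USE.NAMES = FALSE)

  n_err <- integer(n)
  n_dmg <- integer(n)
  if (config@damageCT > 0 || config@seqError > 0) {
    for (i in seq_len(n)) {
      m <- .mutate_fragment(strsplit(template[i], "", fixed = TRUE)[[1]],
                            config@damageCT, config@seqError,
                            config@endWeighted)
      template[i] <- paste(m$chars, collapse = "")
      n_err[i] <- m$n_err
      n_dmg[i] <- m$n_damage
    }
  }

  ids <- sprintf("frag%06d", seq_len(n))

  # duplicates: clone the final read bases so exact-sequence deduplication
  # can remove them; emission probability chosen so the flagged fraction
  # converges to duplicateRate
  p_dup <- if (config@duplicateRate > 0)
    config@duplicateRate / (1 - config@duplicateRate) else 0
  dup <- runif(n) < p_dup
  ord <- rep(seq_len(n), times = 1L + dup)
  is_dup <- unlist(lapply(seq_len(n), function(i)
    if (dup[i]) c(FALSE, TRUE) else FALSE))
  out_ids <- ids[ord]
  out_ids[is_dup] <- paste0(out_ids[is_dup], "_dup")

  qual_string <- function(widths) {
    if (config@lowQualFraction == 0) {
      vapply(widths, function(w) strrep("?", w), character(1))
    } else {
      vapply(widths, function(w) {
        q <- ifelse(runif(w) < config@lowQualFraction, "+", "?")
        paste(q, collapse = "")
      }, character(1))
    }
  }

  truth <- data.frame(
    read_id = out_ids, source_name = nm[src_i][ord],
    source_start = start[ord], strand = strand[ord],
    frag_len = flen[ord], n_seq_errors = n_err[ord],
    n_damage_events = n_dmg[ord], is_duplicate = is_dup,
    stringsAsFactors = FALSE)

  if (config@paired) {
    m1 <- substr(template, 1L, pmin(rl, flen))
    m2 <- vapply(substr(template, pmax(1L, flen - rl + 1L), flen),
                 .revcomp_cpp, character(1), USE.NAMES = FALSE)
    m1 <- m1[ord]; m2 <- m2[ord]
    s1 <- Biostrings::DNAStringSet(m1); names(s1) <- out_ids
    s2 <- Biostrings::DNAStringSet(m2); names(s2) <- out_ids
    q1 <- Biostrings::PhredQuality(qual_string(nchar(m1)))
    q2 <- Biostrings::PhredQuality(qual_string(nchar(m2)))
    reads <- PairedReads(
      Biostrings::QualityScaledDNAStringSet(s1, q1),
      Biostrings::QualityScaledDNAStringSet(s2, q2))
  } else {
    rd <- substr(template, 1L, pmin(rl, flen))[ord]
    ss <- Biostrings::DNAStringSet(rd); names(ss) <- out_ids
    qq <- Biostrings::PhredQuality(qual_string(nchar(rd)))
    reads <- Biostrings::QualityScaledDNAStringSet(ss, qq)
  }

  list(reads = reads, truth = truth)
}

#' Write simulated reads and truth to disk
#'
#' Single-end reads go to `<prefix>.fastq`, pairs to `<prefix>_1.fastq` /
#' `<prefix>_2.fastq`; the truth table to `<prefix>_truth.tsv`.
#'
#' @param sim result of [simulateReads()].
#' @param prefix output path prefix.
#' @return invisibly, the vector of files written
#' @export
writeSimulation <- function(sim, prefix) {
  files <- character(0)
  if (is(sim$reads, "PairedReads")) {
    f1 <- paste0(prefix, "_1.fastq"); f2 <- paste0(prefix, "_2.fastq")
    writeFastq(mate1(sim$reads), f1)
    writeFastq(mate2(sim$reads), f2)
    files <- c(f1, f2)
  } else {
    f <- paste0(prefix, ".fastq")
    writeFastq(sim$reads, f)
    files <- f
  }
  ft <- paste0(prefix, "_truth.tsv")
  writeTsvReport(sim$truth, ft)
  invisible(c(files, ft))
}
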