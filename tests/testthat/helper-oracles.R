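# Shared fixtures and independent oracles.  The oracles are deliberately
# naive full dynamic programs / brute-force enumerations kept separate
# from the package's alignment code paths.

rand_dna <- function(n) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")
}

# minimum-cost fitting alignment (read end-to-end, free target end gaps)
oracle_fit_cost <- function(read, win, mmc = 2, ic = 3, dc = 3) {
  n <- nchar(read); m <- nchar(win)
  rd <- strsplit(read, "")[[1]]; wn <- strsplit(win, "")[[1]]
  D <- matrix(Inf, n + 1, m + 1)
  D[1, ] <- 0
  for (i in 2:(n + 1)) {
    for (j in 1:(m + 1)) {
      v <- D[i - 1, j] + ic
      if (j > 1) {
        sub <- if (rd[i - 1] == wn[j - 1] && rd[i - 1] != "N") 0 else mmc
        v <- min(v, D[i - 1, j - 1] + sub, D[i, j - 1] + dc)
      }
      D[i, j] <- v
    }
  }
  min(D[n + 1, ])
}

# maximum-score global alignment, linear gaps
oracle_global_score <- function(a, b, match = 1, mismatch = -2, gap = -3) {
  n <- nchar(a); m <- nchar(b)
  A <- strsplit(a, "")[[1]]; B <- strsplit(b, "")[[1]]
  D <- matrix(-Inf, n + 1, m + 1)
  D[1, ] <- gap * (0:m); D[, 1] <- gap * (0:n)
  for (i in seq_len(n) + 1) {
    for (j in seq_len(m) + 1) {
      s <- if (A[i - 1] == B[j - 1] && A[i - 1] != "N") match else mismatch
      D[i, j] <- max(D[i - 1, j - 1] + s, D[i - 1, j] + gap,
                     D[i, j - 1] + gap)
    }
  }
  D[n + 1, m + 1]
}

# percent identity of a (possibly rotated / flipped) circular assembly
# against its true source, via exact-anchor rotation and global alignment
assembly_identity <- function(contig_seq, genome) {
  pre <- substr(genome, 1, 40)
  cc <- contig_seq
  dd <- paste0(cc, cc)
  i <- regexpr(pre, dd, fixed = TRUE)
  if (i < 0) {
    cc <- revcomp(cc)
    dd <- paste0(cc, cc)
    i <- regexpr(pre, dd, fixed = TRUE)
  }
  if (i < 0) return(0)
  rot <- paste0(substr(cc, i, nchar(cc)), substr(cc, 1, i - 1))
  al <- globalAlign(genome, rot)
  a <- strsplit(al$a, "")[[1]]; b <- strsplit(al$b, "")[[1]]
  mean(a == b)
}

one_source <- function(seq, name = "src", circular = FALSE, weight = 1) {
  list(list(name = name, seq = seq, circular = circular, weight = weight))
}

as_reads <- function(seqs, prefix = "r") {
  s <- Biostrings::DNAStringSet(seqs)
  names(s) <- sprintf("%s%03d", prefix, seq_along(seqs))
  q <- Biostrings::PhredQuality(strrep("?", nchar(seqs)))
  Biostrings::QualityScaledDNAStringSet(s, q)
}
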