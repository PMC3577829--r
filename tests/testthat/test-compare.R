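test_that("global alignment matches the exhaustive oracle on short pairs", {
  al <- globalAlign("ACGTACGT", "ACGTACGT")
  expect_equal(al$score, 8)
  expect_false(grepl("-", paste0(al$a, al$b)))

  al2 <- globalAlign("ACGTACGT", "ACGACGT")
  expect_equal(nchar(al2$a), 8)
  gaps <- sum(strsplit(al2$b, "")[[1]] == "-") +
    sum(strsplit(al2$a, "")[[1]] == "-")
  expect_equal(gaps, 1)

  set.seed(701)
  for (i in 1:150) {
    a <- rand_dna(sample(1:10, 1))
    b <- rand_dna(sample(1:10, 1))
    expect_equal(globalAlign(a, b)$score, oracle_global_score(a, b),
                 info = paste(a, b))
  }
  expect_error(globalAlign("", "ACGT"), "empty")
})

test_that("nonsynonymous calls agree with translation over all 576 substitutions", {
  bases <- c("A", "C", "G", "T")
  codons <- apply(expand.grid(bases, bases, bases), 1, paste, collapse = "")
  code2 <- Biostrings::getGeneticCode("2")
  for (codon in codons) {
    for (pos in 1:3) {
      for (alt in setdiff(bases, substr(codon, pos, pos))) {
        other <- codon
        substr(other, pos, pos) <- alt
        expected <- code2[[codon]] != code2[[other]]
        expect_identical(isNonsynonymous(codon, pos, alt), expected,
                         info = paste(codon, pos, alt))
      }
    }
  }
})

test_that("circular assemblies rotate and orient onto the anchor gene", {
  g <- as.character(simulateGenome(3000, seed = 91)[[1]])
  ann <- data.frame(region = c("tRNA-Phe", "ND1"), start = c(0L, 100L),
                    end = c(70L, 700L), strand = c("+", "+"),
                    kind = c("tRNA", "CDS"))
  expect_equal(as.character(rotateToStart(g, g, ann)), g)  # identity

  rot <- paste0(substr(g, 1001, 3000), substr(g, 1, 1000))
  r <- rotateToStart(rot, g, ann)
  expect_equal(as.character(r), g)
  expect_equal(attr(r, "offset"), 2000)

  r2 <- rotateToStart(revcomp(rot), g, ann)
  expect_equal(as.character(r2), g)
  expect_true(attr(r2, "flipped"))

  expect_error(rotateToStart(rand_dna(3000), g, ann), "anchor")
})

test_that("annotations project through alignments with indel-aware snapping", {
  g <- as.character(simulateGenome(2000, seed = 92)[[1]])
  ann <- data.frame(region = c("geneA", "geneB"), start = c(100L, 900L),
                    end = c(700L, 1500L), strand = c("+", "+"),
                    kind = c("CDS", "CDS"))
  # identity alignment: coordinates unchanged
  tr0 <- transferAnnotation(globalAlign(g, g), ann)
  expect_equal(tr0$start, ann$start)
  expect_equal(tr0$end, ann$end)
  expect_false(any(tr0$missing | tr0$frame_disrupted))

  # 10 bp insertion before geneA shifts it by +10
  tgt <- paste0(substr(g, 1, 50), strrep("G", 10), substr(g, 51, 2000))
  tr1 <- transferAnnotation(globalAlign(g, tgt), ann)
  expect_equal(tr1$start - ann$start, c(10L, 10L))
  expect_equal(tr1$end - ann$end, c(10L, 10L))

  # in-frame 3 bp deletion shortens the CDS without disrupting the frame
  tgt3 <- paste0(substr(g, 1, 300), substr(g, 304, 2000))
  tr3 <- transferAnnotation(globalAlign(g, tgt3), ann)
  expect_equal(tr3$end[1] - tr3$start[1], 597L)
  expect_false(tr3$frame_disrupted[1])

  # 2 bp deletion disrupts the frame
  tgt2 <- paste0(substr(g, 1, 300), substr(g, 303, 2000))
  tr2 <- transferAnnotation(globalAlign(g, tgt2), ann)
  expect_true(tr2$frame_disrupted[1])
})

test_that("per-region divergence separates syn/nonsyn/gap/ambiguous columns", {
  ann <- data.frame(region = "cds", start = 0L, end = 9L, strand = "+",
                    kind = "CDS")
  # GCC (Ala) -> ACC (Thr): nonsynonymous
  d1 <- regionDivergence(globalAlign("ATGGCCTAA", "ATGACCTAA"), ann)
  expect_equal(d1$segregating_sites, 1L)
  expect_equal(d1$nonsynonymous, 1L)
  # GCC -> GCT: both Ala, synonymous
  d2 <- regionDivergence(globalAlign("ATGGCCTAA", "ATGGCTTAA"), ann)
  expect_equal(d2$segregating_sites, 1L)
  expect_equal(d2$nonsynonymous, 0L)
  # identical regions: all zero
  d3 <- regionDivergence(globalAlign("ATGGCCTAA", "ATGGCCTAA"), ann)
  expect_equal(unlist(d3[c("segregating_sites", "nonsynonymous", "gaps",
                           "ambiguous")], use.names = FALSE), rep(0L, 4))
  # N columns are ambiguous, not segregating
  d4 <- regionDivergence(globalAlign("ATGGCCTAA", "ATGNCCTAA"), ann)
  expect_equal(d4$segregating_sites, 0L)
  expect_equal(d4$ambiguous, 1L)
  # a minus-strand CDS reads its codons off the reverse complement
  annm <- data.frame(region = "cdsm", start = 0L, end = 9L, strand = "-",
                     kind = "CDS")
  a <- revcomp("ATGGCCTAA"); b <- revcomp("ATGACCTAA")
  dm <- regionDivergence(globalAlign(a, b), annm)
  expect_equal(dm$nonsynonymous, 1L)
})

test_that("region rows tile the alignment and counts are symmetric", {
  set.seed(702)
  a <- rand_dna(600)
  b <- a
  for (p in c(50, 200, 450)) {
    substr(b, p, p) <- setdiff(c("A", "C", "G", "T"), substr(b, p, p))[1]
  }
  b <- paste0(substr(b, 1, 300), substr(b, 306, 600))  # 5 bp deletion
  ann <- data.frame(region = c("r1", "r2"), start = c(0L, 300L),
                    end = c(300L, 600L), strand = c("+", "+"),
                    kind = c("rRNA", "rRNA"))
  whole <- data.frame(region = "all", start = 0L, end = 600L,
                      strand = "+", kind = "rRNA")
  al <- globalAlign(a, b)
  parts <- regionDivergence(al, ann)
  total <- regionDivergence(al, whole)
  for (col in c("alignment_length", "segregating_sites", "gaps", "ambiguous"))
    expect_equal(sum(parts[[col]]), total[[col]])

  # symmetry of everything but the codon frame
  alr <- globalAlign(b, a)
  totr <- regionDivergence(alr, data.frame(region = "all", start = 0L,
                                           end = nchar(b), strand = "+",
                                           kind = "rRNA"))
  expect_equal(totr$segregating_sites, total$segregating_sites)
  expect_equal(totr$gaps, total$gaps)
  expect_equal(totr$ambiguous, total$ambiguous)
})

test_that("multi-genome comparison counts sites outside excluded regions", {
  g <- as.character(simulateGenome(4000, seed = 93)[[1]])
  ann <- data.frame(region = c("ND2", "16S", "CR"),
                    start = c(0L, 1000L, 3000L),
                    end = c(999L, 2000L, 4000L),
                    strand = c("+", "+", "+"),
                    kind = c("CDS", "rRNA", "control_region"))
  plant <- function(s, pos) {
    for (p in pos) {
      substr(s, p, p) <- setdiff(c("A", "C", "G", "T"), substr(s, p, p))[1]
    }
    s
  }
  g2 <- plant(g, c(100, 300, 2500))            # 2 outside, 1 outside excl
  g3 <- plant(g, c(700, 1200, 1500, 3100))     # 1 outside, 3 inside excl
  mc <- multiCompare(c(anchor = g, a = g2, b = g3), ann,
                     excludeRegions = c("16S", "CR"))
  expect_equal(mc$segregating_sites, 4L)  # 100, 300, 700 and 2500
  expect_equal(sort(mc$positions), c(99L, 299L, 699L, 2499L))

  # three identical genomes: nothing segregates
  mc0 <- multiCompare(c(x = g, y = g, z = g), ann)
  expect_equal(mc0$segregating_sites, 0L)

  expect_named(mc$pairwise,
               c("anchor vs a", "anchor vs b", "a vs b"))
  expect_equal(names(mc$pairwise[[1]]),
               c("region", "kind", "alignment_length", "segregating_sites",
                 "nonsynonymous", "gaps", "ambiguous", "multi_hit_codons"))
})

test_that("composition reports GATC fractions over unambiguous bases", {
  cp <- composition("ACGT")
  expect_equal(unname(cp$fractions), rep(0.25, 4))
  expect_equal(cp$n_count, 0L)

  cp2 <- composition("AAAN")
  expect_equal(unname(cp2$fractions[["A"]]), 1.0)
  expect_equal(cp2$n_count, 1L)

  expect_error(composition("NNNN"), "all N")
  expect_error(composition(""), "empty")
})
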