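test_that("k-mer counting is canonical and honors the coverage cutoff", {
  set.seed(401)
  r <- rand_dna(60)
  g1 <- buildGraph(c(r, r), assemblyParams(minKmerCount = 1L,
                                           minContigLength = 31L))
  g2 <- buildGraph(c(r, revcomp(r)), assemblyParams(minKmerCount = 1L,
                                                    minContigLength = 31L))
  expect_equal(g1$counts, g2$counts)  # strand-independent multiset

  # a single k-long read gives one node, dropped at the default cutoff 2
  km <- rand_dna(31)
  g3 <- buildGraph(km, assemblyParams(minKmerCount = 1L,
                                      minContigLength = 31L))
  expect_equal(length(g3$counts), 1L)
  expect_equal(unname(g3$counts), 1L)
  g4 <- buildGraph(km, assemblyParams())
  expect_equal(length(g4$counts), 0L)

  expect_error(buildGraph("ACGT", assemblyParams()), "kmerSize")
})

test_that("error-free coverage assembles a linear genome into one exact contig", {
  g <- as.character(simulateGenome(2000, seed = 41)[[1]])
  cfg <- simConfig(seed = 42, nFragments = 600, sources = one_source(g),
                   seqError = 0)
  sim <- simulateReads(cfg)
  ctg <- assemble(sim$reads)
  expect_equal(length(ctg), 1L)
  cc <- consensusSeq(ctg[[1]])
  expect_false(circularHint(ctg[[1]]))
  # exact recovery up to strand; terminal k-mers below the coverage
  # cutoff may trim a few bases off the ends of a linear source
  expect_true(grepl(cc, g, fixed = TRUE) ||
                grepl(cc, revcomp(g), fixed = TRUE))
  expect_gte(nchar(cc), 0.99 * nchar(g))
  # polish leaves an error-free consensus with all-unanimous pileup columns
  tr <- majorAlleleTrack(ctg[[1]])
  expect_true(all(tr$major_freq[tr$depth > 0] == 1))
})

test_that("contigs below the minimum length are discarded", {
  g <- as.character(simulateGenome(250, seed = 43)[[1]])
  cfg <- simConfig(seed = 44, nFragments = 300, sources = one_source(g),
                   seqError = 0, fragmentMean = 100, fragmentSd = 10)
  sim <- simulateReads(cfg)
  graph <- buildGraph(sim$reads, assemblyParams())
  expect_equal(length(extractContigs(graph, assemblyParams())), 0L)
  expect_equal(
    length(extractContigs(graph, assemblyParams(minContigLength = 200L))),
    1L)
})

test_that("a circular genome closes into one circular contig", {
  g <- as.character(simulateGenome(5000, seed = 45)[[1]])
  cfg <- simConfig(seed = 46, nFragments = 2800,
                   sources = one_source(g, circular = TRUE), seqError = 0)
  sim <- simulateReads(cfg)
  ctg <- assemble(sim$reads)
  expect_equal(length(ctg), 1L)
  expect_true(circularHint(ctg[[1]]))
  expect_equal(nchar(ctg[[1]]), 5000L)
  expect_equal(assembly_identity(consensusSeq(ctg[[1]]), g), 1.0)
})

test_that("unlinked sources assemble into separate contigs without chimeras", {
  a <- as.character(simulateGenome(5000, seed = 47)[[1]])
  b <- as.character(simulateGenome(5000, seed = 48)[[1]])
  cfg <- simConfig(seed = 49, nFragments = 5000, seqError = 0, sources = list(
    list(name = "a", seq = a, circular = FALSE, weight = 1),
    list(name = "b", seq = b, circular = FALSE, weight = 1)))
  sim <- simulateReads(cfg)
  ctg <- assemble(sim$reads)
  expect_equal(length(ctg), 2L)
  found <- vapply(ctg, function(x) {
    cc <- consensusSeq(x)
    if (grepl(cc, a, fixed = TRUE) || grepl(cc, revcomp(a), fixed = TRUE))
      "a"
    else if (grepl(cc, b, fixed = TRUE) ||
             grepl(cc, revcomp(b), fixed = TRUE)) "b"
    else "chimera"
  }, character(1))
  expect_setequal(found, c("a", "b"))
  expect_true(all(vapply(ctg, nchar, numeric(1)) >= 4900))
})

test_that("contig count is non-increasing in the minimum contig length", {
  srcs <- lapply(c(400, 800, 2000), function(L)
    list(name = paste0("s", L),
         seq = as.character(simulateGenome(L, seed = L)[[1]]),
         circular = FALSE, weight = 1 / L))
  cfg <- simConfig(seed = 50, nFragments = 4000, seqError = 0,
                   sources = srcs, fragmentMean = 150, fragmentSd = 20)
  sim <- simulateReads(cfg)
  graph <- buildGraph(sim$reads, assemblyParams())
  n <- vapply(c(300L, 500L, 900L, 2100L), function(mcl)
    length(extractContigs(graph, assemblyParams(minContigLength = mcl))),
    numeric(1))
  expect_true(all(diff(n) <= 0))
  expect_equal(n[1], 3)
})

test_that("consensus columns need depth 2 and a untied plurality", {
  set.seed(402)
  g <- rand_dna(400)
  ct <- Contig("c1", g)
  # a single read: every covered column has depth 1 -> N everywhere
  one <- as_reads(substr(g, 101, 190))
  pol <- polish(list(ct), one)
  expect_true(all(strsplit(consensusSeq(pol[[1]]), "")[[1]] == "N"))
  # two agreeing reads: their span is recalled, the rest stays N
  two <- as_reads(c(substr(g, 101, 190), substr(g, 101, 190)))
  pol2 <- polish(list(ct), two)
  cons <- strsplit(consensusSeq(pol2[[1]]), "")[[1]]
  expect_equal(paste(cons[101:190], collapse = ""), substr(g, 101, 190))
  expect_true(all(cons[-(101:190)] == "N"))
  expect_equal(sum(pileup(pol2[[1]])), 180)
})

test_that("pileup totals never exceed the accepted alignment coverage", {
  g <- as.character(simulateGenome(3000, seed = 51)[[1]])
  cfg <- simConfig(seed = 52, nFragments = 900, sources = one_source(g),
                   seqError = 0.004)
  sim <- simulateReads(cfg)
  ctg <- assemble(sim$reads)
  acc <- attr(ctg, "alignments")
  total_aligned <- sum(acc$matches + acc$mismatches)
  expect_lte(sum(pileup(ctg[[1]])), total_aligned)
  expect_gt(sum(pileup(ctg[[1]])), 0)
})

test_that("read pairs join contigs whose ends share an exact overlap", {
  set.seed(403)
  g <- rand_dna(3000)
  A <- substr(g, 1, 1510)      # ends overlap g[1491..1510]
  B <- substr(g, 1491, 3000)
  contigs <- list(Contig("contig_1", A), Contig("contig_2", B))
  # pairs straddling the junction: mate1 left of it, mate2 to the right
  m1 <- character(0); m2 <- character(0)
  for (s in seq(1400, 1420, by = 4)) {
    m1 <- c(m1, substr(g, s, s + 89))
    m2 <- c(m2, revcomp(substr(g, s + 110, s + 199)))
  }
  pr <- PairedReads(as_reads(m1, "p"), as_reads(m2, "p"))
  joined <- mitosalvage:::.join_by_pairs(contigs, pr, assemblyParams())
  expect_equal(length(joined), 1L)
  expect_equal(consensusSeq(joined[[1]]), g)
})
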