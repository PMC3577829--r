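test_that("simulated genomes are reproducible with near-uniform composition", {
  a <- simulateGenome(100, seed = 7)
  b <- simulateGenome(100, seed = 7)
  expect_equal(as.character(a), as.character(b))
  expect_equal(nchar(as.character(simulateGenome(16700, seed = 1)[[1]])),
               16700L)
  expect_error(simulateGenome(0, seed = 1), ">= 1")

  g <- as.character(simulateGenome(1e6, seed = 3)[[1]])
  fr <- table(strsplit(g, "")[[1]]) / 1e6
  sigma <- sqrt(0.25 * 0.75 / 1e6)
  expect_true(all(abs(fr - 0.25) < 3 * sigma))
})

test_that("noise-free reads are exact oriented substrings of their source", {
  g <- as.character(simulateGenome(8000, seed = 5)[[1]])
  cfg <- simConfig(seed = 9, nFragments = 300, sources = one_source(g),
                   seqError = 0)
  sim <- simulateReads(cfg)
  t <- sim$truth
  rd <- as.character(sim$reads)
  for (i in seq_len(nrow(t))) {
    frag <- substr(g, t$source_start[i] + 1, t$source_start[i] + t$frag_len[i])
    tmpl <- if (t$strand[i] == "-") revcomp(frag) else frag
    expect_equal(rd[[i]], substr(tmpl, 1, min(90, t$frag_len[i])))
  }

  # circular sources wrap across the origin
  cfgc <- simConfig(seed = 10, nFragments = 500,
                    sources = one_source(g, circular = TRUE), seqError = 0)
  simc <- simulateReads(cfgc)
  tc <- simc$truth
  wrapped <- tc$source_start + tc$frag_len > nchar(g)
  expect_true(any(wrapped))  # 500 draws should hit the origin
  gg <- paste0(g, g)
  for (i in which(wrapped)) {
    frag <- substr(gg, tc$source_start[i] + 1,
                   tc$source_start[i] + tc$frag_len[i])
    tmpl <- if (tc$strand[i] == "-") revcomp(frag) else frag
    expect_equal(as.character(simc$reads)[[i]],
                 substr(tmpl, 1, min(90, tc$frag_len[i])))
  }
})

test_that("fragment lengths honor the truncated 200 +/- 50 window", {
  g <- as.character(simulateGenome(50000, seed = 6)[[1]])
  cfg <- simConfig(seed = 2, nFragments = 2000, sources = one_source(g))
  sim <- simulateReads(cfg)
  fl <- sim$truth$frag_len
  expect_true(all(fl >= 150 & fl <= 250))
  expect_true(abs(mean(fl) - 200) < 3 * 25 / sqrt(2000) + 1)
})

test_that("injected substitutions follow the configured binomial rate", {
  g <- as.character(simulateGenome(50000, seed = 8)[[1]])
  cfg <- simConfig(seed = 4, nFragments = 5000, sources = one_source(g),
                   seqError = 0.004)
  sim <- simulateReads(cfg)
  nb <- sum(sim$truth$frag_len)  # errors are injected along the fragment
  ne <- sum(sim$truth$n_seq_errors)
  sigma <- sqrt(nb * 0.004 * 0.996)
  expect_lt(abs(ne - nb * 0.004), 3 * sigma)
})

test_that("source sampling follows weight x length (coverage ratio)", {
  mito <- as.character(simulateGenome(5000, seed = 11)[[1]])
  nuc <- as.character(simulateGenome(200000, seed = 12)[[1]])
  cfg <- simConfig(seed = 13, nFragments = 20000, seqError = 0, sources = list(
    list(name = "mito", seq = mito, circular = TRUE, weight = 500),
    list(name = "nuclear", seq = nuc, circular = FALSE, weight = 1)))
  sim <- simulateReads(cfg)
  t <- sim$truth
  cov <- tapply(t$frag_len, t$source_name, sum)
  ratio <- (cov[["mito"]] / 5000) / (cov[["nuclear"]] / 200000)
  expect_lt(abs(ratio - 500) / 500, 0.10)
})

test_that("duplicates clone final read bases at the configured rate", {
  g <- as.character(simulateGenome(100000, seed = 14)[[1]])
  cfg <- simConfig(seed = 15, nFragments = 5000, sources = one_source(g),
                   seqError = 0.004, duplicateRate = 0.2)
  sim <- simulateReads(cfg)
  t <- sim$truth
  fr <- mean(t$is_duplicate)
  expect_lt(abs(fr - 0.2), 3 * sqrt(0.2 * 0.8 / nrow(t)))
  # a clone is byte-identical to the read preceding it
  rd <- as.character(sim$reads)
  i <- which(t$is_duplicate)
  expect_true(all(rd[i] == rd[i - 1]))
})

test_that("damage hits only template-strand C positions", {
  g <- as.character(simulateGenome(20000, seed = 16)[[1]])
  cfg <- simConfig(seed = 17, nFragments = 400, sources = one_source(g),
                   seqError = 0, damageCT = 0.05)
  sim <- simulateReads(cfg)
  t <- sim$truth
  rd <- as.character(sim$reads)
  n_ct <- 0
  for (i in seq_len(nrow(t))) {
    frag <- substr(g, t$source_start[i] + 1, t$source_start[i] + t$frag_len[i])
    tmpl <- if (t$strand[i] == "-") revcomp(frag) else frag
    clean <- strsplit(substr(tmpl, 1, nchar(rd[[i]])), "")[[1]]
    obs <- strsplit(rd[[i]], "")[[1]]
    diffs <- which(clean != obs)
    # every difference is a C (template) read as T
    expect_true(all(clean[diffs] == "C" & obs[diffs] == "T"))
    n_ct <- n_ct + length(diffs)
  }
  expect_gt(n_ct, 0)
})

test_that("low-quality base fraction drives the Q20 percentage", {
  g <- as.character(simulateGenome(20000, seed = 18)[[1]])
  cfg <- simConfig(seed = 19, nFragments = 1000, sources = one_source(g),
                   lowQualFraction = 0.1)
  sim <- simulateReads(cfg)
  qc <- qcSummary(sim$reads)
  expect_lt(abs(qc$pct_q20 - 90), 1)
})

test_that("paired mode emits the 5' read and the reverse-complemented 3' end", {
  g <- as.character(simulateGenome(10000, seed = 20)[[1]])
  cfg <- simConfig(seed = 21, nFragments = 200, sources = one_source(g),
                   seqError = 0, paired = TRUE)
  sim <- simulateReads(cfg)
  expect_s4_class(sim$reads, "PairedReads")
  t <- sim$truth
  m1 <- as.character(mate1(sim$reads)); m2 <- as.character(mate2(sim$reads))
  for (i in seq_len(5)) {
    frag <- substr(g, t$source_start[i] + 1, t$source_start[i] + t$frag_len[i])
    tmpl <- if (t$strand[i] == "-") revcomp(frag) else frag
    expect_equal(m1[[i]], substr(tmpl, 1, 90))
    expect_equal(m2[[i]],
                 revcomp(substr(tmpl, t$frag_len[i] - 89, t$frag_len[i])))
  }
})
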