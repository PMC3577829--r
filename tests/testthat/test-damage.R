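mk_spectrum <- function(rates, opportunity = 1e5) {
  # build a spectrum whose per-opportunity rates equal `rates`
  counts <- stats::setNames(numeric(12), mitosalvage:::MISMATCH_TYPES)
  counts[names(rates)] <- rates * opportunity
  opp <- stats::setNames(rep(opportunity, 4), c("A", "C", "G", "T"))
  new("MismatchSpectrum", counts = counts, opportunities = opp,
      totalMismatch = sum(counts), totalAligned = 4 * opportunity)
}

test_that("the error rate divides mismatch bases by aligned bases", {
  # count form (used for published worked examples)
  expect_equal(round(errorRate(6995, 1663480), 4), 0.0042)
  expect_equal(round(errorRate(13032, 3178345), 4), 0.0041)
  expect_error(errorRate(10, 0), "zero aligned")

  # alignment-table form
  set.seed(601)
  t <- c(cons = rand_dna(1000))
  reads <- vapply(seq(1, 900, by = 90), function(s)
    substr(t, s, s + 89), character(1))
  substr(reads[1], 10, 10) <-
    setdiff(c("A", "C", "G", "T"), substr(reads[1], 10, 10))[1]
  aln <- mapReads(reads, t, damageMapperParams())
  expect_equal(errorRate(aln), 1 / (10 * 90))
  clean <- mapReads(reads[-1], t, damageMapperParams())
  expect_equal(errorRate(clean), 0)
})

test_that("the spectrum counts directed mismatches per consensus base", {
  set.seed(602)
  t <- c(cons = rand_dna(200))
  cpos <- which(strsplit(unname(t), "")[[1]] == "C")
  read <- substr(t, 1, 120)
  hit <- cpos[cpos <= 120][1:5]
  for (p in hit) substr(read, p, p) <- "T"
  aln <- mapReads(read, t, damageMapperParams())
  sp <- mismatchSpectrum(aln, t)
  expect_equal(unname(mismatchCounts(sp)[["C>T"]]), 5)
  nC <- sum(strsplit(substr(t, 1, 120), "")[[1]] == "C")
  expect_equal(unname(mismatchRates(sp)[["C>T"]]), 5 / nC)
  expect_equal(sum(mismatchCounts(sp)), 5)
  # conservation: rates weighted by opportunities give back the counts
  r <- mismatchRates(sp)
  from <- substr(names(r), 1, 1)
  expect_equal(sum(r * sp@opportunities[from]), sp@totalMismatch)

  # zero-mismatch alignments: all 12 counts zero
  sp0 <- mismatchSpectrum(mapReads(substr(t, 11, 100), t,
                                   damageMapperParams()), t)
  expect_true(all(mismatchCounts(sp0) == 0))
})

test_that("the damage flag needs both C>T and G>A elevated over the rest", {
  base <- stats::setNames(rep(2e-3, 12), mitosalvage:::MISMATCH_TYPES)
  expect_false(damageFlag(mk_spectrum(base))$flag)

  up <- base; up[c("C>T", "G>A")] <- 3 * 2e-3
  expect_true(damageFlag(mk_spectrum(up))$flag)

  boundary <- base; boundary[c("C>T", "G>A")] <- 2.0 * 2e-3
  expect_false(damageFlag(mk_spectrum(boundary))$flag)
  expect_true(damageFlag(mk_spectrum(boundary), fold = 2.0)$flag)

  bad <- mk_spectrum(base)
  bad@opportunities[["A"]] <- 0
  expect_error(damageFlag(bad), "opportunity")
})

test_that("damage-only simulation concentrates the spectrum on C>T and G>A", {
  g <- simulateGenome(20000, seed = 81)
  cfg <- simConfig(seed = 82, nFragments = 2000,
                   sources = one_source(as.character(g[[1]])),
                   seqError = 0, damageCT = 0.01)
  sim <- simulateReads(cfg)
  aln <- mapReads(sim$reads, g, damageMapperParams())
  sp <- mismatchSpectrum(aln, g)
  r <- sort(mismatchRates(sp), decreasing = TRUE)
  expect_setequal(names(r)[1:2], c("C>T", "G>A"))
  # all other categories stay at (binomially) zero
  expect_true(all(r[3:12] < 3 * sqrt(0.01 / min(sp@opportunities))))
  expect_true(damageFlag(sp)$flag)
  expect_true(damageFlag(sp)$combined_below_1pct)
})

test_that("allele summaries cover polymorphic pileup columns", {
  pu <- matrix(0L, 4, 3, dimnames = list(c("A", "C", "G", "T"), NULL))
  pu["A", 1] <- 9L; pu["G", 1] <- 1L
  pu["C", 2] <- 8L; pu["T", 2] <- 2L
  pu["T", 3] <- 10L
  s <- alleleSummary(pu)
  expect_equal(s$n_polymorphic_sites, 2L)
  expect_equal(s$mean, 0.85)
  expect_equal(s$min, 0.8)
  expect_equal(s$max, 0.9)

  mono <- matrix(c(5L, 0L, 0L, 0L), 4, 1,
                 dimnames = list(c("A", "C", "G", "T"), NULL))
  expect_equal(alleleSummary(mono)$n_polymorphic_sites, 0L)
})

test_that("major-allele frequencies stay near 1 at realistic error rates", {
  g <- as.character(simulateGenome(4000, seed = 83)[[1]])
  cfg <- simConfig(seed = 84, nFragments = 4500,  # ~100x in 90 bp reads
                   sources = one_source(g, circular = TRUE),
                   seqError = 0.004)
  sim <- simulateReads(cfg)
  ctg <- assemble(sim$reads)
  s <- alleleSummary(ctg[[1]])
  expect_gt(s$n_polymorphic_sites, 0)
  expect_gte(s$mean, 0.98)
})
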