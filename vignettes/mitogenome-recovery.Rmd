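---
title: "Recovering mitogenomes from degraded shotgun libraries: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Recovering mitogenomes from degraded shotgun libraries}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>", eval = FALSE)
```

# The problem

DNA from archival specimens is short (fragments around 200 ± 50 bp),
chemically damaged (post-mortem cytosine deamination, read as C→T on the
template strand and G→A on its complement), redundant (PCR duplicates),
and mixed with exogenous human, fungal and bacterial DNA. Two properties
still make the mitochondrial genome recoverable without any reference
assembly: it is small (~16–17 kb, circular in vertebrates) and present at
high copy number per cell, so in a shotgun library its reads outnumber
any single-copy nuclear locus by one to two orders of magnitude. The
package turns that into a pipeline: deduplicate, assemble *de novo*,
find the contig whose coverage is an extreme outlier, check contamination
and damage, and compare the result to reference mitogenomes.

`mitosalvage` couples every stage to a ground-truth simulator so the
whole chain is testable: each simulated read knows its source genome,
position, strand, injected errors, damage events, and duplicate status.

# The simulator

`simConfig()` / `simulateReads()` emulate the library design end to end:

* **Fragments.** Lengths are normal(200, 25) truncated to the ±50 bp
  window and floored at 30 bp; origins are uniform over each source,
  wrapping across the origin for circular sources; sources are drawn with
  probability proportional to `weight × length`, so `weight` is a
  per-copy abundance. Template strand is uniform.
* **Reads.** Single-end mode reports the fragment 5′ end, paired mode the
  5′ end plus the reverse complement of the 3′ end, each clipped to the
  90 bp read length (shorter when the fragment is shorter, in which case
  mates overlap).
* **Damage before error.** Each template-strand C becomes T with
  probability `damageCT`; because the template strand is random, half of
  the damage appears as G→A after orientation onto the source plus
  strand. Damage is uniform along the fragment by default; an optional
  end-weighted mode (exponential decay from the 5′ end, scale 20 bp,
  renormalised to preserve the mean rate) reproduces the end-enrichment
  seen in heavily degraded material, but stays off because the default
  study conditions make no positional claim.
* **Sequencing error after damage.** Each base substitutes to a uniform
  different base with probability `seqError` (default 0.004, the
  HiSeq-era substitution regime). Indel sequencing errors are not
  simulated: substitution dominates on this platform and the pipeline's
  cost model penalises indels more heavily anyway.
* **Duplicates.** A fragment is re-emitted with probability
  `d/(1−d)` so the *fraction* of duplicate-flagged reads converges to
  `duplicateRate = d`. Crucially, duplicates clone the **final** read
  bases (post-error): they model re-sequencing of one library molecule,
  which is exactly what exact-sequence deduplication can remove.
* **Qualities.** Constant Q30, with an optional `lowQualFraction` of
  bases at Q10 to exercise the %Q20 summary. Base-call errors are not
  coupled to qualities; the pipeline uses qualities only for QC
  summaries.
* **Seeding.** One RNG stream per configuration seed; every run is
  reproducible.

The default mito:nuclear abundance used in examples and tests (weights
chosen to give the mitochondrial source a fold-enrichment of 50–500) is a
free parameter of the simulation — the true cellular ratio in archival
tissue is unknown and varies — so tests assert *relative* behaviour
(the mito contig is the coverage outlier) rather than a particular ratio.

What the simulator does **not** emulate, and what passing tests therefore
do not show about real data: real genome composition and repeats (sources
are uniform-random, so assembly never faces long repeats, homopolymer
artifacts or nuclear copies of mitochondrial sequence), indel errors,
quality-correlated errors, end-enriched damage (off by default), and
library-preparation biases. The pipeline's correctness on these inputs is
a statement about its logic, not about every pathology of archival DNA.

# Read placement

The mapper is a seed-and-extend fitting aligner under the cost model
mismatch 2, insertion 3, deletion 3 (minimised). Exact 15-mers over both
strands propose diagonals; a banded dynamic program (half-width 15)
aligns the read end to end against the local window, with free end gaps
on the target. Two published acceptance knobs gate a placement:

* **similarity** — matches / alignment columns (gap columns count
  against it), threshold 0.97 for assembly-stage mapping and 0.9 for
  contamination panels (0.97 for a human panel, where specificity against
  human contamination is the point);
* **overlap** — aligned read bases / read length, threshold 0.5. A read
  overhanging a contig end is clipped to the overlapping part, which is
  what lowers this fraction below 1.

The named thresholds come from the tool conventions of this field; their
internal definitions are not published anywhere authoritative, so the two
interpretations above are this package's documented choice. `N` never
matches: it costs a mismatch and can never raise similarity.

One placement per read is reported. Ties break deterministically: most
matches, lowest cost, lowest target, lowest start, plus strand. All
coordinates are 0-based half-open internally and converted only in
reports.

# Assembly

A standard de Bruijn assembler replaces the closed commercial tool used
in this workflow's origins; the published knobs are honoured where they
act (mapping-back costs and thresholds; contigs ≥ 300 bp):

* **Graph.** Canonical k-mers (lexicographic minimum of k-mer and
  reverse complement), k = 31 by default (odd, so no k-mer is its own
  reverse complement); k-mers containing N are skipped; multiplicity
  below `minKmerCount = 2` is dropped, which removes the overwhelming
  majority of singleton error k-mers.
* **Cleaning.** Three rules, iterated to a fixed point (≤ 5 rounds):
  tips (dead-end unitigs shorter than 2k) are pruned; simple bubbles —
  parallel unitigs sharing both attachment nodes, equal length, ≤ 2
  mismatches — collapse onto the higher-coverage branch; and short
  unitigs whose coverage falls below 1/8 of the backbone coverage
  (length-weighted median unitig coverage) are removed. The third rule
  matters at high coverage: at 100× with 0.4% error, hundreds of error
  k-mers reach multiplicity 2 by coincidence and form branch structures
  that are neither clean tips nor clean bubbles; they sit 20–30-fold
  below the backbone and are unambiguous at that separation. The 1/8
  factor is conservative — legitimate low-coverage unitigs in a 4–8×
  nuclear background sit far above 1/8 of their own backbone.
* **Contigs.** Maximal unambiguous paths. A path that closes into a
  cycle is emitted once, trimmed of its duplicated (k−1)-overlap, with
  `circularHint = TRUE`. Reported orientation is deterministic: circular
  contigs start at the lexicographically minimal rotation of the
  lexicographically smaller strand (Booth's algorithm); linear contigs
  take the smaller strand. `rotateToStart()` re-rotates circular contigs
  onto a biological anchor (by convention the first base of tRNA-Phe)
  for reporting.
* **Polish.** Every read is mapped back (similarity 0.97, overlap 0.5);
  accepted placements accumulate a per-site A/C/G/T pileup; the consensus
  is the plurality base, or N where depth < 2 or the plurality is tied.
  The N rule is a deliberate floor: a single read never certifies a base.
  One polish pass suffices at the error rates in scope.
* **Pairs.** Pairing does not enter graph construction (canonical k-mers
  are strand-free); in paired mode, contigs bridged by ≥ 5 read pairs are
  joined when their ends share an exact overlap of ≥ 20 bp. Gapped
  scaffolding is out of scope: the target molecule is a single small
  circle, and a gap would have to be closed by the graph anyway.

Two edge behaviours are worth knowing. First, the ends of a *linear*
source lose a few terminal bases: terminal k-mers are covered by fewer
reads and fall under `minKmerCount`; the effect is invisible on circular
molecules, which have no ends. Second, `coverageMode()` bins average
coverages at one decimal and breaks ties toward the smaller value, making
the triage fold `avg_coverage / mode` reproducible to the digit.

# Triage, contamination, damage

**Triage.** Candidates for the mitogenome are contigs ≥ 10 kb whose
coverage is ≥ 10× the modal contig coverage; the longest candidate is
flagged. The 10× fold floor is this package's default (observed
enrichments in real libraries of this kind run 25–47×); it is exposed as
a parameter. Identification by coverage deliberately replaces database
searches — no network, no taxonomy; an optional alignment to a
user-supplied reference mitogenome (the compare module) confirms
identity.

**Contamination.** Each read is mapped *independently* against each
panel entry with that entry's similarity threshold; a read counts toward
every entry it hits, so percentages may overlap and need not sum to 100.
This mirrors how such screens are actually run (one mapping per
reference set). An `exclusive = TRUE` mode assigns each read to its
best entry for users who need a partition. Panel entries can be declared
`proxy` (a related species standing in for an unavailable genome) — a
documentation flag only.

**Damage.** The error rate is substitution-only: mismatching bases over
aligned bases, with inserted/deleted bases in neither numerator nor
denominator, computed against the consensus under assessment. The
12-category spectrum orients every read onto the consensus plus strand
first, so template-strand deamination lands in C→T and G→A. Rates are
reported under two normalisations — per opportunity (count / aligned
consensus-X columns), which makes cross-category comparison well-defined
under unequal base composition, and per total mismatch; the flag uses
per-opportunity. `damageFlag()` fires when C→T and G→A are each ≥ 2.5×
the median of the other ten rates, and separately reports whether the
combined damaged share of aligned bases stays below 1% (the regime where
damage cannot meaningfully distort a high-coverage consensus). Damage
assessment maps reads at similarity 0.9, not 0.97: a 90 bp read with ≥ 3
mismatches would be rejected at 0.97, censoring exactly the reads that
carry the signal and biasing the error estimator downward. Reads are
assessed post-deduplication in the pipeline order; duplicates would
simply re-count the same molecule.

# Comparison

Whole-mitogenome alignment is a banded global alignment under match 1,
mismatch −2, gap −3 (linear). The scores are this package's choice — the
GUI tools historically used for such comparisons publish no scheme — and
are configurable; the band half-width defaults to
`max(200, |length difference| + 50)`, ample for near-identical
mitogenomes. Traceback is deterministic (diagonal, then gap in the first
sequence, then gap in the second).

Annotation transfer projects region endpoints through alignment columns;
endpoints landing in target gaps snap inward; regions wholly deleted are
flagged missing; transferred CDS lengths not divisible by 3 are flagged
frame-disrupted. Per-region divergence counts, per alignment column:
segregating sites (both bases unambiguous, non-gap, different), gap
characters, N-containing columns (ambiguous, and excluded from the
segregating count), and — for CDS — the nonsynonymous subset under the
vertebrate mitochondrial genetic code (AGA/AGG stop, ATA Met, TGA Trp),
each segregating site evaluated independently against the first
sequence's codon. Codons hit by more than one substitution are counted
site-by-site and flagged (`multi_hit_codons`); none are expected between
conspecific mitogenomes, but the flag makes the convention auditable.

Multi-genome comparison projects every genome onto the first (anchor)
through pairwise alignments rather than building a full multiple
alignment: for three near-identical ~17 kb sequences, anchor projection
is exact where it matters, deterministic, and cheap. Sites are counted
where *all* genomes carry unambiguous non-gap bases and at least two
differ, with named regions (conventionally the gap-rich 16S rRNA, ND6
and control region) excludable. The cost of this choice is that
insertions relative to the anchor are invisible to the site count — the
right trade for near-identical genomes, and stated here so nobody
mistakes the output for an MSA-based count.

# Numerical and testing choices

Determinism is enforced everywhere randomness is not explicit: graph
traversal iterates k-mers in sorted order, alignment tracebacks have
fixed tie preferences, mapping ties break lexicographically, and every
simulation takes a seed. Degenerate inputs are values, not crashes:
an unmapped read is a row with `mapped = FALSE`; an empty candidate list
is an empty table; zero aligned bases, empty panels and all-N sequences
are errors because no meaningful statistic exists.

Test and acceptance problem sizes are chosen to exercise the study
conditions at desk scale: the full assembly checks run a 16.7 kb circular
genome at ~100× (about 9,300 read pairs), recovery checks use 20–50 kb
sources with 3,000–6,000 fragments, and oracle checks compare the
alignment engines against exhaustive dynamic programs on all-pairs
short strings and all 576 single-base codon substitutions. Sample-level
statistics of any particular real library (read counts in the tens of
millions, per-sample contamination percentages) are functions of that
library and are not reproducible from simulation; what the suite
certifies is that each estimator recovers the quantity it estimates on
inputs where the truth is known.

# Limitations

* No numt awareness: a high-copy nuclear mitochondrial insertion with
  coverage comparable to the mitogenome would pass triage; the
  allele-frequency track (near-1 major alleles) is the available
  diagnostic.
* No affine gaps, no quality-aware alignment, no SAM/BAM output.
* Assembly cleaning assumes substitution-dominated noise; indel-rich
  platforms would need different bubble handling.
* The multi-genome segregating-site count is anchor-projected, not
  MSA-based (see above).
* Damage positional profiles (rate versus position in read) are out of
  scope; the spectrum is genome-wide.
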