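# mitosalvage

Reference-free recovery and quality control of mitochondrial genomes from
shotgun sequencing of degraded DNA — the kind of short (~200 ± 50 bp),
chemically damaged, heavily contaminated material that comes out of museum
skins and other archival specimens.

The package is aimed at researchers who have (or simulate) short-read
shotgun libraries from such material and want to:

- remove PCR-duplicate reads and summarise read quality (count, %Q20);
- assemble reads *de novo* into contigs (de Bruijn graph over canonical
  *k*-mers, tip/bubble cleaning, pileup-polished consensus) in paired-end
  or single-end mode;
- identify the mitochondrial contig without any database search, from its
  coverage excess: with `C` the average coverage of a contig and
  `C̃` the modal contig coverage, the mitogenome stands out by
  `fold = C / C̃ ≫ 1`, a direct consequence of mitochondrial copy number;
- profile exogenous contamination by mapping reads independently against a
  user-supplied reference panel (host proxy, human, fungal, bacterial),
  each panel entry with its own identity threshold;
- quantify post-mortem damage: the overall mismatch rate of raw reads
  against the consensus, `e = mismatching bases / aligned bases`, and the
  twelve directed mismatch categories `X→Y`, normalised per opportunity
  `r(X→Y) = n(X→Y) / n(aligned consensus-X columns)`. Cytosine
  deamination shows up as `r(C→T)` and `r(G→A)` elevated several-fold over
  the median of the other ten categories;
- compare assembled mitogenomes to references: anchored rotation of
  circular contigs, annotation transfer through a global alignment,
  per-region counts of segregating sites / nonsynonymous substitutions
  (vertebrate mitochondrial code) / gaps / ambiguous sites, and base
  composition.

Read placement uses the cost model mismatch 2, insertion 3, deletion 3,
with acceptance thresholds on *similarity* (matches / alignment columns,
default 0.97; 0.9 for contamination panels) and *aligned read fraction*
(default 0.5).

A seeded simulator (`simulateReads()`) generates the whole study design —
circular high-copy mitogenome over a nuclear background, 200 ± 50 bp
fragments sequenced as 90 bp reads, per-base error ~0.004, strand-aware
C→T deamination, PCR duplicates, contaminant admixture — with a per-read
ground-truth table, so every stage is testable end to end with no
downloads.

## Worked example

```r
library(mitosalvage)

# a 16.7 kb circular "mitogenome" at high copy number, read as 90 bp
# paired-end shotgun reads with 0.4% sequencing error and mild
# cytosine deamination
mito <- simulateGenome(16700, seed = 7, circular = TRUE)
cfg <- simConfig(seed = 8, nFragments = 9300, paired = TRUE,
                 seqError = 0.004, damageCT = 0.005,
                 sources = list(list(name = "mito",
                                     seq = as.character(mito[[1]]),
                                     circular = TRUE, weight = 1)))
sim <- simulateReads(cfg)
sim$reads
#> PairedReads with 9300 pairs
#>   mate widths: 90-90 bp

contigs <- assemble(sim$reads, assemblyParams(), paired = TRUE)
contigs[[1]]
#> Contig contig_1 : 16700 bp (circular)
#>   average coverage: 98.98

als <- alleleSummary(contigs[[1]])
#> polymorphic sites: 6305 (mean major-allele freq 0.987)

reads <- c(as.character(mate1(sim$reads)), as.character(mate2(sim$reads)))
aln <- mapReads(reads, contigs, params = damageMapperParams(),
                circular = TRUE)
errorRate(aln)
#> 0.0053

spec <- mismatchSpectrum(aln, contigs[[1]])
spec
#> MismatchSpectrum: 8878 mismatches over 1673910 aligned bases
#>   highest per-opportunity rates: C>T, G>A
damageFlag(spec)$flag
#> TRUE   (C>T + G>A share of aligned bases: 0.19%)
```

Reading the numbers: the ~9,300 fragment pairs give ~100× coverage of the
16.7 kb circle, and the assembler returns it as a single circular contig.
About 6,300 of the 16,700 pileup columns show a minor allele, but the
major allele still averages 98.7% — the signature of a homoplasmic source
observed through ~0.5% read-level noise, not of mixed haplotypes. The raw
read error rate (0.0053) is the sequencing error plus the injected
deamination; the spectrum attributes the excess specifically to C→T and
its complementary-strand mirror G→A, and the damage flag fires while the
combined damaged share stays far below 1% of aligned bases — damage is
detectable but too rare to threaten the consensus.

Other entry points: `removeDuplicates()` / `qcSummary()` (read QC),
`identifyMito()` / `coverageLengthTable()` (coverage triage),
`profileContamination()` (panel profiling), `globalAlign()`,
`rotateToStart()`, `transferAnnotation()`, `regionDivergence()`,
`multiCompare()`, `composition()` (mitogenome comparison), and
`readFastq()` / `readFasta()` / `readFeatureTable()` /
`writeTsvReport()` for IO. The methods vignette
(`vignettes/mitogenome-recovery.Rmd`) documents the models, parameter
choices and limitations.

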