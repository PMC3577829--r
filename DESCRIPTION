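Package: mitosalvage
Title: Reference-Free Mitogenome Recovery and Quality Control from
    Degraded Shotgun Sequencing Libraries
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org",
           role = c("aut", "cre"))
Description: Recovers complete mitochondrial genomes from shotgun
    sequencing of degraded (e.g., ancient or museum-specimen) DNA without
    a reference assembly. Provides exact-sequence duplicate removal and
    read-level quality summaries, a de Bruijn graph assembler with
    pileup-based consensus polishing, identification of the mitochondrial
    contig by its coverage excess over the modal contig coverage,
    metagenomic contamination profiling against user-supplied reference
    panels, quantification of post-mortem deamination damage through the
    twelve directed mismatch categories, and per-region divergence tables
    between mitogenomes under the vertebrate mitochondrial genetic code.
    A ground-truth shotgun read simulator for circular high-copy genomes
    over a nuclear background (fragment-length distribution, sequencing
    error, cytosine deamination, PCR duplicates, contaminant admixture)
    makes the whole pipeline testable end to end.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    methods,
    stats,
    utils,
    Rcpp,
    Biostrings
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    jsonlite
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Collate: 
    'AllClasses.R'
    'RcppExports.R'
    'mapper.R'
    'assembler.R'
    'compare.R'
    'contamination.R'
    'damage.R'
    'dedup.R'
    'formats-io.R'
    'simulate.R'
    'triage.R'
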