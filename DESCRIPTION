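Package: methref
Title: Reference-Genome-Aware DNA Methylation Array and Sequencing Analysis
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "maintainer@example.org", role = c("aut", "cre"))
Description: Tools for evaluating Illumina DNA methylation array probes
    against one or many genome assemblies via in-silico alignment to
    bisulfite-converted genome variants, classifying probes as unambiguous,
    cross-reactive or mismatched, and deriving pangenome consensus and
    population-specific unambiguous probe sets. Also provides CpG
    enumeration and island detection, coverage-filtered CpG calling from
    cytosine reports, chain-file coordinate liftover and cross-reference
    CpG-set comparison, an epigenome-wide association analysis with a
    permutation-based false discovery rate, and genomic-element,
    repeat-category, driver-gene and gene-set enrichment statistics.
    Includes seeded synthetic-data generators with machine-readable planted
    truth so every stage is testable without external downloads.
License: MIT + file LICENSE
Encoding: UTF-8
Depends: R (>= 4.1)
Imports:
    stats,
    utils,
    Biostrings,
    IRanges
Suggests:
    testthat (>= 3.0.0),
    rtracklayer,
    GenomicRanges,
    knitr,
    rmarkdown
Config/testthat/edition: 3
RoxygenNote: 7.3.3
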