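# methref

Reference-genome-aware analysis of DNA methylation array probes and
bisulfite sequencing CpGs.

## The problem

Illumina methylation arrays (HM450K / EPIC / EPICv2) measure DNA
methylation by hybridising 50-nt probes to bisulfite-converted DNA, so the
trustworthiness of every probe depends on the reference assembly it is
evaluated against. A probe whose sequence aligns acceptably to more than
one locus is **cross-reactive**; a probe with no acceptable alignment whose
target CpG dinucleotide matches perfectly is **mismatched**; the remainder
are **unambiguous**. As reference genomes improve (complete
telomere-to-telomere assemblies, pangenome haplotype panels), these sets
shift — and so do the CpGs callable from sequencing data, the loci an EWAS
can test, and the enrichment statistics built on top of them.

`methref` is an R package for epigenomics analysts that implements this
evaluation end to end:

* **Probe classification** — gapless seed-and-extend alignment of probe
  sequences (with Cartesian expansion of degenerate `R` bases) against four
  bisulfite-converted genome variants: all-C→T and CpG-preserving
  conversions of both strands. A hit qualifies with ≥ 40/50 matching bases,
  ≥ 90% identity and no gaps; qualifying hits are collapsed into physical
  loci (± 2 bp) and each probe is called `unambiguous`, `cross_reactive`
  or `mismatched` — a strict partition of the manifest. The target CpG
  dinucleotide must be perfectly matched for an alignment to count as
  "good".
* **Pangenome consensus** — integration of per-assembly classifications
  into consensus sets (unambiguous in ≥ ⌈0.95 N⌉ of N assemblies; all
  assemblies when N < 5), population/subpopulation sets, and four-way
  comparisons between two references with Table-style summaries.
* **CpG calling & comparison** — CpG enumeration, classic-definition CpG
  island detection (≥ 200 bp, GC > 50%, observed/expected CpG > 0.6),
  coverage-filtered calling from Bismark-style cytosine reports, strand
  merging, chain-file liftover and cross-reference CpG-set comparison.
* **EWAS** — per-site Mann-Whitney testing with two FDR regimes: a
  permutation FDR (label shuffles; the largest observed p-value with
  estimated FDR ≤ 5% becomes the significance threshold) and
  Benjamini-Hochberg, both combined with a |Δβ| > 0.10 effect filter;
  replicate-variability and array-vs-WGBS difference metrics.
* **Enrichment** — promoter / gene-body / island / shore / shelf
  annotation, 2×2 chi-squared element enrichment, prioritised repeat
  categories (segdup > LINE/SINE > satellite > other), permutation-based
  driver-gene enrichment and a local hypergeometric over-representation
  test.
* **Synthetic data** — seeded generators for assembly panels (planted
  segmental duplications, satellites, CpG islands, extra sequence blocks
  with an exactly emitted chain), probe manifests with planted classes,
  and two-group beta matrices with planted DMCs, replicate noise and
  matching cytosine reports — every pipeline stage is testable without
  downloads, against machine-readable truth.

## Worked example

```r
library(methref)

# a synthetic assembly with planted duplications, plus a planted manifest
pan <- generate_assembly_panel(seed = 42)
pm  <- generate_probe_manifest(pan$base,
                               dup_intervals     = pan$tracks$segdup,
                               exclude_intervals = pan$tracks$satellite,
                               n_unambiguous = 20, n_cross_reactive = 20,
                               n_mismatched = 20, seed = 101)
res <- classify_manifest(pm$manifest, pan$base)
#> classified 60 probes: unambiguous=20, cross_reactive=20, mismatched=20
table(planted = pm$truth$planted_status, called = res$status)
#>                 called
#> planted          cross_reactive mismatched unambiguous
#>   cross_reactive             20          0           0
#>   mismatched                  0         20           0
#>   unambiguous                 0          0          20
```

Every planted probe is recovered in its class: probes copied from inside a
planted duplication report two collapsed loci (`n_loci = 2`), probes with a
damaged target cytosine keep a qualifying 49/50 alignment but fail the
CpG-dinucleotide check, and 11-substitution probes fall below the 40-match
floor.

```r
# permutation-FDR EWAS on planted differential methylation
d  <- generate_methylation_dataset(n_sites = 2000, dmc_frac = 0.05,
                                   delta = 0.3, seed = 7)
dm <- call_dmcs(d$betas, d$groups, params = meth_params(n_perm = 200),
                fdr_mode = "permutation", seed = 7)
#> tested 2000 sites, 92 significant (permutation mode)
attr(dm, "p_threshold")
#> [1] 0.003610514
sum(dm$significant & d$truth$is_dmc[match(dm$site, d$truth$site)])
#> [1] 92
```

Of 100 planted DMCs (Δβ = 0.3, 10 cases vs 10 controls), 92 are recovered
at the permutation-derived p-value threshold of 3.6 × 10⁻³, with no false
positives among the 92 calls in this run — the threshold is the largest
observed p-value whose estimated false discovery rate stays at or below
5%.

See `vignettes/methref-methods.Rmd` for the full model description,
parameter meanings and defaults, the synthetic-data assumptions, and known
limitations.

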