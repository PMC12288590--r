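---
title: "Methods: reference-genome-aware methylation probe evaluation and EWAS"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: reference-genome-aware methylation probe evaluation and EWAS}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(methref)
```

# Scope and model

Illumina methylation arrays (HM450K, EPIC, EPICv2) read out DNA methylation
by hybridising 50-nt probes to bisulfite-converted DNA. Whether a probe's
signal can be trusted depends on how its sequence relates to the reference
assembly it is evaluated against: a probe whose sequence has acceptable
alignments at more than one locus is *cross-reactive*; a probe with no
acceptable alignment covering its declared target CpG is *mismatched*; the
remainder are *unambiguous*. `methref` implements this trichotomy as an
in-silico alignment procedure against one or many assemblies, integrates
per-assembly results into pangenome consensus and population-specific probe
sets, and surrounds the classifier with the companion analyses such probe
sets feed: CpG calling from cytosine reports, coordinate liftover and
cross-reference CpG-set comparison, a permutation-FDR EWAS, and
genomic-element / repeat / gene-set enrichment statistics.

## The four converted genome variants

Bisulfite chemistry converts unmethylated cytosine to (sequenced) thymine
and leaves methylated cytosine intact. Because array probes are designed
against converted DNA of either strand and either methylation state, probe
alignment is performed against four variants of each assembly:

1. `unmeth_fwd` — every C converted to T;
2. `meth_fwd` — only non-CpG Cs converted (CpG cytosines presumed
   methylated and protected);
3. `unmeth_rev`, 4. `meth_rev` — the same two conversions applied to the
   reverse complement, i.e. to the other strand.

N bases pass through unchanged and never match anything. Hits found on the
reverse variants are reported in forward source coordinates with strand
`-`, so one coordinate frame serves all downstream locus book-keeping.

## Alignment and qualification

The aligner is a gapless seed-and-extend: genome tiles of 11 bases sampled
every 5 bases are hashed (tiles occurring more than 10^6 times are masked,
which is inert at the scales used here but kept for fidelity to the
configuration it mirrors); every probe 11-mer proposes a diagonal, and each
distinct placement is scored over its in-bounds span. A placement qualifies
with at least 40 matching bases *and* at least 90% identity, with no gaps.
Gapped alignment is deliberately absent: a hit with a gap could never
satisfy the no-gap qualification rule, so the machinery would be dead
weight. The identity denominator is the in-bounds aligned span, which is
what lets the two thresholds be non-redundant for probes overhanging a
contig end: such a probe can reach 90% identity yet fail the 40-base floor.

Like any tile-indexed aligner, the seed stage can in principle miss a
qualifying placement none of whose sampled 11-mers survives intact (at
least four well-placed mismatches are needed). The test-suite therefore
checks soundness (every reported hit re-verifies under an exhaustive
scorer), completeness for full-length matches, and classification-level
agreement with the exhaustive oracle on planted manifests.

## The trichotomy

For each probe, qualifying hits are collected over all four variants and
over the Cartesian expansion of any degenerate `R` base (replaced by A and
G, as type II chemistry permits). Hits are then collapsed into physical
loci: hits on the same contig whose starts lie within 2 bp of the cluster
anchor are one locus. This collapsing is essential — the same physical
locus is necessarily discoverable in complementary variants and in both R
expansions, and counting it repeatedly would label nearly every probe
cross-reactive.

A probe has a *good alignment* when at least one collapsed locus overlaps
its declared target and, for some constituent hit, both bases of the target
CpG dinucleotide are aligned and identical between the probe (complemented
for minus-strand hits) and the *source* genome — the CpG must be perfect
even though the rest of the alignment tolerates mismatches. Classification
is then: no good alignment → `mismatched`; good alignment and exactly one
locus → `unambiguous`; otherwise `cross_reactive`. Qualifying loci that
fail the CpG test at non-target positions still count toward uniqueness;
the CpG perfection requirement applies to the target-defining hit only. A
probe declaring a contig absent from the assembly can have no good
alignment and is reported `mismatched` rather than raising an error.

## Consensus and population sets

Against a panel of haplotype-level assemblies, a probe enters the consensus
unambiguous set when it is unambiguous in at least `ceiling(0.95 × N)`
assemblies. The ceiling is the only reading of "no less than 95%" that
never admits a smaller fraction. For sparsely represented groups (N < 5)
the rule tightens to all assemblies. Population and subpopulation sets
apply the same rule to the assemblies carrying each label. Four-way
comparison of two references (both / A-unique / B-unique / neither) is a
strict partition of the manifest, and summaries report percentages to one
decimal and fold ratios to two, matching the precision conventions of the
tabulations they emulate.

# CpG calling, islands, liftover

`enumerate_cpgs()` records the 0-based position of the C of every
forward-strand CG; CpG is palindromic, so this single-strand enumeration is
complete. `call_cpgs()` keeps a site only when its total read count reaches
the coverage floor (default 10×) in *every* sample, optionally restricted
to a configurable autosome list (synthetic assemblies have arbitrary contig
names, so nothing is inferred from names). `merge_cpg_strands()` folds
minus-strand (G-position) calls onto the C position and recomputes the
beta; calls not at a reference CpG are left alone with a warning.

CpG islands follow the classic compositional definition: regions of at
least 200 bp with GC content above 50% and observed/expected CpG ratio
above 0.6, with expected = #C × #G / length. The caller slides a 200-bp
window at step 1, merges overlapping or abutting qualifying windows, and
re-verifies each merged region against both thresholds, dropping failures.
Windows with more than 10% N are ineligible — a conservative choice where
no rule is prescribed. This is a definition-driven algorithm; the UCSC
browser's island track is produced by a different procedure and is
deliberately not reproduced.

Liftover consumes UCSC chain files into a block table (reverse-strand query
blocks are normalised to forward coordinates at read time, so downstream
point mapping needs one orientation only). A position inside an aligned
block maps by block offset; positions in inter-block gaps or on absent
contigs are unmapped. This single-chain block mapping is the desk-scale
counterpart of running the UCSC liftOver tool with default parameters; a
test cross-checks it against `rtracklayer::liftOver` on the
generator-emitted chain. In cross-reference CpG comparisons, calls that
fail to lift cannot intersect anything and count toward the unlifted side's
unique set.

# EWAS statistics

Per-site differential methylation uses the two-sided Mann-Whitney U test.
The scalar front end enumerates the exact null when the smaller group has
at most 8 observations and no ties, and otherwise uses the normal
approximation with tie and continuity corrections. Inside the permutation
FDR, both observed and permuted p-values come from one identical
vectorised formula (row ranks are computed once; only rank sums change
under label permutation), so exceedance counts are comparable by
construction; this path requires a complete matrix, and sites with missing
values should be dropped first.

The permutation FDR shuffles group labels `n_perm` times preserving group
sizes, and for a candidate threshold t estimates
FDR(t) = mean over permutations of #{p_perm ≤ t} / max(1, #{p_obs ≤ t}).
The reported threshold is the largest observed p-value with FDR(t) at or
below the target (5% by default); when none qualifies there are zero
discoveries. Permutations are sampled uniformly without enforcing
distinctness, and the observed labelling is not included in the null set —
with 10-vs-10 designs repeated draws are rare and the estimator stays
unbiased. A site is a DMC when it passes the active FDR rule
(permutation threshold, or Benjamini-Hochberg adjusted p below 0.05) *and*
|Δβ| exceeds 0.10, where Δβ is the case mean minus the control mean; the
absolute value is used because hyper- and hypomethylation both count.

Technical reproducibility is summarised as the per-site sample standard
deviation across replicates (n−1 denominator), and cross-platform
agreement as the absolute array-minus-sequencing beta difference over
shared sites after excluding sequencing sites below the coverage floor.
Group-wise metric comparisons use the same Mann-Whitney test with BH
adjustment across the requested comparison family.

# Enrichment statistics

Sites are annotated with strand-aware promoters (2 kb upstream of the
transcription start), gene bodies, and mutually exclusive island / shore /
shelf flags assigned by distance band from the nearest island edge (0,
(0, 2 kb], (2 kb, 4 kb]); shores and shelves are measured from island
edges, not midpoints, and a site equidistant between two islands resolves
to the lower-coordinate island, which cannot change its band. Promoter and
body flags are per-gene, so a site inside overlapping annotations may
carry both.

Element enrichment is the target-over-background proportion ratio with a
2×2 Pearson chi-squared test (no continuity correction) per feature and BH
adjustment across features. Repeat categories resolve by fixed priority —
segmental duplication, then merged LINE/SINE, then satellite, then other
repeat — mirroring the removal of lower-priority overlaps from each track.
Driver-gene enrichment draws `n_perm` uniform gene samples of the target's
size from the universe; fold is observed over mean permuted overlap and
the p-value uses the add-one estimator (1 + exceedances)/(1 + n_perm),
which avoids p = 0 and matches the resolution of a 1,000-permutation test.
Pathway over-representation is a local one-sided hypergeometric test on
user-supplied gene sets with BH adjustment and significance at adjusted
p < 0.05 — a network-free substitute for web-service enrichment tools,
making no attempt to reproduce their custom backgrounds or bespoke
multiple-testing variants.

# Synthetic data and what the tests do (and do not) show

The generators define the conditions under which every stage is exercised:

* **Assemblies.** A two-contig backbone (20 kb + 6 kb by default) with
  planted CpG-rich island-like segments, satellite-like tandem repeats and
  verbatim segmental duplications; a "complete" assembly that additionally
  carries two 800-bp insert blocks (CpG-dense at one end), with the
  base-to-complete chain emitted exactly from the edit script — truth must
  be exact, so the chain is never re-derived by alignment. Insert
  junctions are padded and placed so they can neither create nor destroy a
  CpG, which makes the complete-minus-base CpG count exactly the insert
  CpG count, a property the tests exploit. Haplotypes add SNVs at 10^-3
  per base and an optional population-private duplication. Base
  composition is uniform with planted CpG-dense segments; real genomes'
  isochore structure, repeat families and mutation spectra are not
  modelled.
* **Manifests.** 20 probes per class by default: unambiguous probes copied
  verbatim from the CpG-preserving converted genome at mutually distant
  unique loci; cross-reactive probes copied from inside planted
  duplications; mismatched probes either carry one substitution at the
  target cytosine (alignment qualifies at 49/50, CpG test fails) or 11
  substitutions (39/50, below the qualification floor). A configurable
  fraction of probes is designed against the minus strand, and some type
  II probes carry a planted degenerate R at an original A/G position, so
  one expansion restores the exact sequence.
* **Methylation.** Beta values follow a Beta distribution in the
  mean/precision parameterisation (precision 50) around per-site means in
  (0.05, 0.95); planted DMCs separate group means by the configured Δβ
  (0.3 in the power checks, clipped into (0.02, 0.98) with the clip
  recorded); cytosine reports draw binomial counts at Poisson(30)
  coverage; technical replicates add Gaussian noise (SD 0.02). These are
  the simplest standard models for the two modalities; probe-type effects,
  batch structure and cell-type mixtures are intentionally absent.

Passing tests therefore demonstrate algorithmic correctness — exact
planted-truth recovery, agreement with exhaustive and enumeration oracles,
calibration and power under clean noise models — not performance on real
cohorts, where repeat content, probe chemistry and confounding are harsher.

# Numerical choices and problem sizes

Internal coordinates are uniformly 0-based half-open; the 1-based inputs
(Illumina MAPINFO positions, Bismark coverage reports) are shifted exactly
once at the reader boundary. Beta values are always recomputed from counts
rather than trusted from percentage columns (disagreements beyond 0.5
percentage points warn, and counts win). Zero-total sites keep a missing
beta rather than a fabricated one. The locus-collapsing tolerance is
±2 bp. Consensus thresholds use ceilings on assembly counts. The test and
acceptance workloads use 20–26 kb genomes, 60-probe manifests, 2,000-site
beta matrices with 10-vs-10 groups, 200 permutations for the permutation
FDR and 10–20 seed replicates — sizes chosen so the planted effects are
comfortably identifiable while the full suite runs in minutes on one core.

# Known limitations

* The seed index can miss heavily mutated secondary placements without a
  surviving sampled tile (shared with the aligner family it mirrors).
* The "extension base" flavour of probe mismatch — a discrepancy in the
  single base read after the probe's 3' end — requires next-base manifest
  annotations that the classifier does not consume; it is not evaluated,
  and the mismatched class is not silently broadened to include it.
* Liftover is single-chain block mapping; multi-chain netting and
  inversion-aware mapping are out of scope.
* The permutation FDR implements the plug-in estimator described above;
  an alternative per-CpG permutation null (retaining each site's most
  significant permuted p) is a defensible different reading and is noted
  as unimplemented.
* Population-level consensus behaviour is validated on synthetic panels
  only; the real pangenome's per-population composition is not modelled.
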