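---
title: "TSS-centered occupancy analysis: models, parameters and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{TSS-centered occupancy analysis: models, parameters and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tssoccupancy)
```

## The analysis in one paragraph

`tssoccupancy` quantifies how a repressive chromatin mark (H3K27me3, written
by the EZH2/PRC2 complex) is distributed around gene promoters, and how that
distribution shifts between genotypes. Starting from per-sample coverage
pileups (bedGraph) and a refGene gene annotation, the pipeline (i) scales
each pileup to one million mappable reads so libraries are comparable,
(ii) averages the scaled signal in 100-bp bins across ±5 kb of each gene's
transcription start site (TSS), (iii) partitions all genes into four
occupancy classes by k-means on those bin profiles, ordered from high to low
modification level, (iv) compares per-cluster metagene profiles between
genotypes, (v) asks how a gene set of interest (e.g. neuronal genes defined
by their ontology annotations) distributes across the clusters and which
annotation terms are enriched in a cluster (EASE score with
Benjamini–Hochberg control), and (vi) provides the matching ΔΔCt
relative-expression statistics for follow-up qPCR designs.

## Coordinates and the TSS anchor

All genomic coordinates follow the UCSC refGene convention: 0-based,
half-open `[tx_start, tx_end)`. The TSS of a plus-strand gene is
`tx_start`; for a minus-strand gene it is `tx_end - 1`, the last covered
base. Each gene is represented by its single longest transcript
(`select_longest_transcripts()`); length ties break deterministically by
`(chrom, tx_start, transcript_id)`. A gene symbol that appears on several
chromosomes is collapsed to the genome-wide longest transcript with a
warning — the analysis treats "gene" as one unit, and keeping both copies
would double-count rows in the occupancy matrix.

## Coverage model

A `CoverageTrack` is piecewise-constant with implicit zeros: bedGraph files
omit uncovered regions, so any base not covered by an interval has signal 0,
including bases beyond the last interval and whole chromosomes absent from
the file. Signal stays on the linear scale throughout; no log transform or
smoothing is applied before binning. `scale_to_million()` multiplies every
value by `1e6 / mappable_reads`; what counts as a "mappable read" (before or
after duplicate removal) is deliberately left to the caller, who supplies
the denominator.

The qualitative question "did the enzyme's binding sites redistribute
between genotypes?" is operationalized as `track_similarity()`: Pearson
correlation of the two tracks' mean signals over a genome-wide grid of
1-kb bins. Correlation is scale-free, so it specifically measures
redistribution rather than global gain or loss.

## The occupancy matrix

With the default `occupancy_config()` (half-window `W = 5000` bp, bin width
`b = 100` bp) each gene contributes `B = 2W/b = 100` bins. For a plus-strand
gene, bin `i` (1-based) covers `[tss - W + (i-1)b, tss - W + ib)`; the bin
immediately downstream of the TSS starts at the TSS itself. Rows of
minus-strand genes are mirrored so that bin 1 is always the gene's 5' flank:
bin `i` covers `[tss + W - ib, tss + W - (i-1)b)`. Whether the original
analysis flipped minus-strand genes is not knowable from its outputs (all
four archetype shapes are symmetric around the TSS); the flip is this
package's choice, because metagenes are direction-meaningful, and it can be
disabled with `orient_strand = FALSE`.

Bins that would extend past chromosome position 0 contribute zeros (the
implicit-zero convention applied out of range) and set the gene's
`edge_clipped` flag; genes are never dropped, so cluster counts always
cover the full annotation. Genes on chromosomes missing from a track get
all-zero rows plus a warning rather than an error — in practice this is a
contig-naming mismatch the user should see but not be stopped by.

## Clustering

`kmeans_occupancy()` runs Lloyd k-means with squared Euclidean distance on
the raw bin profiles. Three numerical choices matter:

* **No standardization.** The classes are defined "from high to low
  modification level"; per-row scaling would erase exactly the quantity the
  partition is supposed to order, so profiles enter as-is.
* **Initialization and determinism.** Each of the `restarts` (default 10)
  runs starts from k-means++ seeding; rows are processed in
  gene-name-sorted order and all draws come from a caller-supplied seed, so
  the gene→label map is reproducible and invariant to input row order. The
  best run by within-cluster sum of squares wins. A cluster that empties
  during iteration is re-seeded from the point farthest from its centroid
  (logged), rather than aborting.
* **Label order.** Labels are renumbered by descending cluster mean
  occupancy, so cluster 1 is always the heavily marked broad-domain class
  and cluster 4 the unmarked class, whatever the internal k-means labels
  were.

The partition is fit on the wild-type matrix only; the mutant matrix is
grouped through `apply_assignment()` with no re-clustering. Fitting on one
genotype and projecting the other keeps the cluster definitions fixed, so
genotype differences show up in the metagenes instead of being absorbed
into shifted cluster boundaries. Joint or mutant-side fitting is possible
by passing a different matrix to `kmeans_occupancy()`; nothing downstream
assumes which genotype defined the partition.

`k = 4` is fixed by design (broad domain / strong TSS summit / weak TSS
summit / unmarked); the package does no model selection over `k`.

## Metagenes and genotype differences

`metagene_profile()` is the per-bin arithmetic mean across the selected
genes with the standard error of the mean attached; a single gene yields
its own row with SEM 0. `genotype_difference()` reports per-bin
`mutant - wild-type` with SEM propagated as `sqrt(sem_wt^2 + sem_mut^2)`.
The differences are descriptive: the upstream analysis draws qualitative
conclusions from these curves, and the package deliberately adds no per-bin
hypothesis testing. Exact identities hold by construction and are tested:
the metagene of a union of disjoint groups is the size-weighted mean of the
group metagenes, and the difference operator is antisymmetric.

## Gene sets and EASE enrichment

A gene is classified "neuronal" if any of its annotation terms contains
"synapse" or "synaptic" (case-insensitive substring, any ontology branch),
or a cellular-component term contains "neuron". The rule — not any
particular annotation release's gene list — is what the package
reproduces; the annotation table is an input, and the shipped generator's
tables are synthetic.

Term enrichment uses the EASE score: the one-sided Fisher's exact
(hypergeometric upper-tail) p-value computed after replacing the overlap
count `a` with `max(a - 1, 0)`. The decrement makes single-gene overlaps
uninformative (`p = 1`) and is uniformly conservative relative to plain
Fisher — a property the test suite verifies by full enumeration over all
2×2 tables with margins ≤ 12. Only enrichment (upper tail) is tested.
Benjamini–Hochberg step-up adjustment runs across all tested terms via
`stats::p.adjust`, with significance called at adjusted p < 0.05 by
default. The enrichment background defaults to the clustered gene universe
and is overridable.

## ΔΔCt expression statistics

For the unpaired genotype design, the mean wild-type ΔCt (`dct_mean`) is
the normalizer and every sample's relative expression is
`2^-(dct - dct_mean)`; wild-type folds therefore have log2 mean exactly 0
(geometric mean 1). Genotypes are compared per gene with the classical
equal-variance Student's t test — "Student's t", not Welch — on the fold
values. For the paired vehicle/drug design, each pair's fold is
`2^-(dct_drug - dct_vehicle)` with the vehicle side 1 by construction, and
folds are tested against 1 with a two-sided paired (one-sample) t test.
Testing on the fold scale matches the quantity the field plots; a
`scale = "ddct"` alternative (one-sample t on ΔΔCt against 0) is provided
and documented as not the default presentation. Technical replicates are
averaged on the Ct scale before ΔCt. Zero-variance inputs return `t = 0`,
`p = 1` with a warning instead of failing, so noise-free simulated tables
flow through the same code path.

## The synthetic-data generator

Real deposited pileups are tens of millions of reads against a full mouse
annotation; the generator is a statistical stand-in that makes every stage
testable offline with known ground truth. It emulates:

* **Four occupancy archetypes** — broad plateau (`h_broad = 8` signal
  units across the whole ±5 kb window), strong TSS summit (Gaussian,
  `h_strong = 12`, σ = 500 bp), weak TSS summit (`h_weak = 4`, σ = 500 bp)
  and unmarked baseline (`b = 0.5`) — in proportions
  0.02 / 0.10 / 0.55 / 0.33, loosely echoing observed cluster-size
  fractions. These are fixture choices, not measured values.
* **A genotype effect**: the mutant multiplies the broad-class amplitude by
  `1 + 0.3` and both summit amplitudes by `1 - 0.3`, reproducing the
  qualitative pattern of a broad-domain gain with TSS-summit loss.
* **Depth noise**: per-100-bp segment values are drawn
  `Poisson(expectation × depth/1e6)` and the declared mappable read count
  equals `depth`, so `scale_to_million()` recovers the expectation scale.
  The default depth is 5 million reads — small enough for desk-scale runs,
  deep enough that archetypes are cleanly separable. A variance-zero mode
  (`noise = "none"`) exists for exact tests.
* **Layout**: one synthetic chromosome, alternating strands, TSS positions
  on the 100-bp grid and ≥ 11.2 kb apart so gene windows never overlap.
  That alignment makes noise-free matrix rows reproduce the archetype
  shapes exactly, which the tests exploit.
* **Annotation-term tables** with optional planted "synaptic"/"neuron"
  terms whose members are drawn with elevated odds from the summit
  classes, plus uniform null terms for calibration; and **Ct tables** with
  a fixed reference gene and a planted ΔCt shift.

What the generator does *not* emulate — and hence what passing tests do not
demonstrate about real data: mappability and GC artifacts, fragment-size
effects, overlapping or nested genes, chromosome-scale domain structure,
replicate-to-replicate biological variability, and asymmetric promoter
shapes. Results on real pileups depend on those factors; the tests
establish correctness of the computation, not robustness to every artifact.

## Problem sizes and reproducibility

The shipped checks run the full pipeline at 600–1000 genes, 10 restarts and
10 simulation seeds, sizes at which every property of interest (archetype
recovery with adjusted Rand index ≥ 0.9, sign recovery of the planted
genotype effects in ≥ 9/10 seeds, ~5 % null calibration of EASE over 1000
terms) is already stable; `scripts/acceptance.R` recomputes them from
scratch for any `--seed`. All randomness flows from explicit seeds through
an RNG-state-preserving wrapper, so every simulated object is bit-for-bit
reproducible and library calls never disturb the caller's RNG stream.

## Known limitations

* Gene-body/meta-length scaling is out of scope: profiles are strictly
  TSS-anchored.
* No peak calling, breadth calling or per-bin inference; cluster shapes are
  descriptive.
* Single-reference-gene ΔΔCt without amplification-efficiency correction.
* EASE enrichment does no ontology-graph propagation; terms are flat sets.
* `track_similarity` is a global statistic; it will not localize a
  redistribution, only detect its absence or presence.
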