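---
title: "Null models and pairwise gene similarity analyses for TADs"
author: "tadnull"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Null models and pairwise gene similarity analyses for TADs}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(tadnull)
suppressPackageStartupMessages(library(GenomicRanges))
```

## The scientific problem

Topologically associating domains (TADs) are genomic regions with
elevated internal Hi-C contact frequency. A recurring claim is that
genes sharing a TAD are functionally related — co-expressed, sharing
Gene Ontology terms, pathways, protein–protein interactions (PPIs), or
descended from common ancestors (paralogs). The confound is the linear
genome itself: genes that share a TAD are *close*, and close genes are
functionally similar for reasons that have nothing to do with chromatin
domains (tandem duplication, shared regulatory neighbourhoods).

`tadnull` implements the null-model machinery needed to separate these
effects, together with the pairwise similarity metrics and the ensemble
permutation statistics used to compare real TADs against their nulls.
Everything is exercised end to end on synthetic genomes with known,
planted structure.

## The two null models

**Positional randomisation ("random TADs").** Each TAD is relocated,
in shuffled order, to a uniformly drawn region of its own chromosome
with *identical bp length* and *exactly the same number of
strictly-contained genes*. This preserves TAD size, gene count and,
implicitly, local gene density — so a difference between real and
random TADs cannot be explained by those covariates. Placement is
rejection sampling: a uniform candidate start is accepted iff the gene
count matches and the overlap rules hold; every rejected proposal
consumes one attempt, and a TAD with no accepted placement after
`maxAttempts` (default 10,000) proposals is excluded from that set (the
exclusion count is recorded per set). Partition-style (TopDom-like)
sets forbid any overlap among relocated TADs. Overlapping-style
(Arrowhead-like) sets always accept *nested* candidates (closed
containment either way, boundary ties included) and accept candidates
with at least one *non-nested* overlap with probability
`nonNestedProb` (default 0.10) — a single Bernoulli draw per candidate,
not per overlapped partner, reflecting that the acceptance probability
is a property of the proposed placement.

**Genome randomisation ("random genomes").** Gene *identities* are
permuted uniformly within each chromosome; every coordinate and every
TAD stays fixed. Per chromosome, the multiset of coordinates and of
ids is exactly preserved, hence so is every TAD's gene count. This
null removes all signal attached to gene identity while keeping the
linear geometry; used together with positional randomisation, it
separates "genes in TADs are similar" from "nearby genes are similar".

**Comparison randomisers.** Two published strategies are implemented
for benchmarking. The *span-based, length-shrinking* method relocates a
TAD with k genes to the exact span of a random run of k consecutive
genes, accepted when the span does not exceed the source length —
regions are spans of genes, so this method cannot produce zero-gene
TADs, and zero-gene sources are skipped. The *gap-avoiding* method
relocates each TAD uniformly at identical length, rejecting candidates
that intersect assembly gaps, with no gene-count constraint. On
fixtures with heterogeneous gene spacing, `compareRandomizers()` shows
that the positional method reproduces the real intergene-distance
distribution most closely (smallest absolute median effect size),
because it is the only one matching the joint (length, count)
constraint.

## Gene assignment and TAD annotation

Genes are assigned to a TAD only when both their start and end fall
inside it (strict containment); boundary-straddling genes belong to no
TAD, and with nested TADs a gene belongs to every TAD containing it.
TADs are classified *CTCF* when some ChIP-seq peak interval intersects
the window boundary ± one 10 kb bin at **both** boundaries, with
one-boundary and zero-boundary cases jointly forming the nonCTCF class.
Whole peak intervals are used rather than summits — robust to wide
peaks, since only a "within ± 10 kb" rule is defined. Compartment
labels are assigned by majority base-pair overlap with the A/B track;
exact ties and zero overlap give "unassigned" rather than an arbitrary
label. Occupancy classes count contained genes as 1–5 with 6 and more
collapsed to "6+", zero-gene TADs excluded. Per-TAD constraint is the
arithmetic mean over the nonsynonymous z-scores of **all transcripts**
of all contained genes (per-transcript pooling; a per-gene-mean variant
is available but non-default).

## Pairwise metrics

Within-TAD gene pairs are the union over TADs of each TAD's unordered
pairs, with duplicates collapsed — which realises the nested/overlap
deduplication rules (nested TADs contribute the enclosing TAD's pairs
once; pairs in a region shared by partially overlapping TADs appear
once). Metrics are NA metric-by-metric, never row-wise:

* **Co-expression**: FPKM values below 1 are floored to 0, then
  Spearman's rank correlation (average ranks for ties) across samples;
  pairs with a constant floored vector are NA. More than three samples
  are required.
* **GO semantic similarity**: term information content is the standard
  corpus frequency under the true-path rule, IC(t) = −ln p(t),
  normalised to [0, 1] by the corpus maximum (IC(root) = 0). The term
  similarity is the bounded Jiang measure
  sim = 1 − min(1, IC(t1) + IC(t2) − 2·IC(MICA)) with the MICA taken
  over the reflexive common ancestors; gene scores combine term sets by
  best-match average. Genes with no usable terms give NA. Molecular
  function is the intended default namespace of the corpus; any
  single-rooted ontology table works.
* **Shared pathways / PPIs**: a pair shares a pathway iff the pathway
  sets intersect; NA when either gene is unannotated, so proportions
  are always over pairs with at least one annotation each. The default
  PPI semantics is a *direct edge* between the two genes (the
  conservative reading of "sharing an interaction"); a shared-partner
  mode is available behind an explicit argument and never silently
  mixed.
* **Paralogy**: pairs present in the paralog table; removable as a
  filter or testable as 2×2 enrichment against null pairs.

Genome-wide, `genomewideDistanceBins()` bins all same-chromosome pairs
by start-to-start distance (default log-spaced edges 10 kb–10 Mb plus
an overflow bin; fully configurable since no canonical edges exist)
and compares each bin's summary against the same summary in N permuted
genomes with the one-sided permutation p-value
(number of null summaries ≥ real)/N, FDR-corrected across bins within
each metric.

## Inference

All distribution comparisons use the two-sided Mann–Whitney/Wilcoxon
rank-sum test: tie-corrected variance, continuity correction (on by
default, toggleable), exact enumeration for tie-free samples with
n ≤ 16. The z statistic is retained because the reported effect size is
r = |z|/√n, signed positive when the TAD-side median exceeds the
null side. Count comparisons use Fisher's exact test (two-sided,
fixed-margin hypergeometric); its effect-size analogue is the signed
phi coefficient. The *ensemble scheme* tests the real data against each
of N null sets separately and reports the median p-value and median
signed r (for an even N, the mean of the two central order
statistics). Degenerate 2×2 tables (a zero margin, e.g. no paralog
pair on either side) contribute p = 1, r = 0: no evidence either way.
Benjamini–Hochberg correction is applied within one analysis family
(all distance bins of one metric; all 15 occupancy contrasts), never
across analyses. Permutation p-values of exactly 0 are legitimate
under the counting formula and are displayed as "< 1/N".

### A note on the calibration of the median-p decision

The median-p over an ensemble is *not* a 5%-level test. The per-set
p-values share the real sample, so they are strongly positively
correlated; simulation with fully independent Gaussian samples shows
that P(median of 25 per-set p-values < 0.05) ≈ 0.007 under the null,
essentially independent of the per-set sample size. The decision rule
is therefore conservative by construction — a desirable property for
the screening use it is put to, but worth knowing: the *per-set*
p-values are the quantity with nominal 5% calibration (verified in the
test suite to reject at a rate within [0.02, 0.09] under a true null),
while the median-p decision rejects far less often.

## The synthetic-data generator

`simulateAll()` builds a complete study: chromosomes with
non-overlapping genes, a TAD tiling with configurable inter-TAD gaps
(gaps create boundary-straddling genes, exercising the strict
assignment rule), optional nested TADs for the overlapping style, CTCF
peaks placed within one bin of each boundary independently with
probability `pCtcf`, alternating A/B compartment blocks, tandem and
dispersed paralog families, a copula-based expression matrix, planted
annotation sharing, and per-transcript constraint scores with a
singleton-TAD shift. One seed reproduces every output exactly.

Design choices that matter:

* **Expression planting is rank-based**: latent Gaussian profiles are a
  variance-weighted sum of a shared per-TAD factor (share `rhoTad`,
  optionally restricted to CTCF TADs), an AR(1) distance-decaying
  factor (share `decayWeight`, correlation length `decayScale`), and
  white noise; the latent value is pushed through a monotone log-normal
  map calibrated so that an expected `floorFraction` of values falls
  below 1 FPKM. Because the map is monotone, Spearman targets survive
  the flooring.
* **Gene layouts**: `uniform` (default) places genes uniformly;
  `gradient` decays gene density along the chromosome;
  `clustered` places tandem gene runs inside TADs with margins, with
  larger families denser than small ones — the size-dependent spacing
  emulates real tandem arrays and is what gives the three randomisers
  distinguishable intergene-distance behaviour. Both methods that match
  gene counts effectively sample runs of consecutive genes, and they
  become exactly equivalent when within-TAD spacing is homogeneous, so
  a fixture without density heterogeneity cannot express the ordering
  seen on real genomes.
* **Annotation sharing** is planted so the realised pairwise sharing
  probabilities match the configured ones. Background sharing comes
  from the vocabulary itself: each annotated gene carries one own leaf
  term and one own pathway drawn from pools of size
  1/`backgroundShare`, so two random genes collide at exactly the
  background rate (unique annotations when the background is zero).
  Within-TAD sharing comes from a per-TAD leaf and a fresh per-TAD
  pathway given to each member gene with probability q, with q²
  compounding with the background to `annotationShare`; PPI edges are
  planted directly per pair. Keeping term sets small (at most a few
  leaves per gene) matters: appending terms per forced pair would
  dilute the best-match-average score and wash out the planted GO
  signal. A fraction of genes is left unannotated to exercise every NA
  path.

What the generator does **not** emulate: Hi-C contact matrices (nulls
operate at the interval/annotation level), realistic chromosome-scale
gene counts, GC or replication-timing structure, and ontologies deeper
than two levels. Passing tests therefore demonstrate the correctness
and calibration of the machinery, not biological conclusions about any
real genome.

## Problem sizes used in the shipped tests

The test-suite study conditions are small synthetic genomes (one to
four chromosomes of ~0.8–1.6 Mb, 15–70 genes per chromosome, 25–30
null sets per ensemble, 100–200 replicates for calibration and power)
— sizes at which every expected value in the oracle tests can be
enumerated or simulated exactly, and the full pipeline runs in seconds
per replicate. The ensemble size of 100 used in real studies is
exercised directly in the ensemble unit tests; the running-median
convergence diagnostic (`convergenceReport()`) is the tool for judging
whether an ensemble was large enough.

## Worked example

```{r example, eval = FALSE}
cfg <- simulationConfig(seed = 7, geneLayout = "clustered",
                        rhoTad = 0.6, rhoTadCtcfOnly = TRUE,
                        annotationShare = 0.5, backgroundShare = 0.05,
                        tandemFraction = 0.8, pCtcf = 0.9)
d <- simulateAll(cfg)
bundle <- runPipeline(d, nSets = 25, seed = 1, nRandomGenomes = 200)
cat(renderReport(bundle), sep = "\n")
```

## Known limitations

* Rejection sampling can exclude TADs whose constraints are very tight
  (dense gene clusters on crowded chromosomes); exclusion counts are
  recorded per set and downstream comparisons use placed TADs only, as
  no re-weighting rule is defined.
* Exact-test discreteness makes the Fisher-based comparisons
  conservative when annotated-pair counts are small; at desk scale the
  pathway/PPI calibration sits below nominal.
* The overlapping-style occupancy analysis treats nested TADs
  independently (each gets its own class); whether shared genes should
  be deduplicated there is genuinely open, and the pair-level analyses
  are unaffected because pair deduplication happens at enumeration.
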