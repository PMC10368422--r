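---
title: "Methods: regional chromatin-accessibility analysis with clonatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: regional chromatin-accessibility analysis with clonatlas}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

## What the package models

`clonatlas` analyses ATAC-seq of micro-dissected brain compartments
("clonal units"): many small samples, each labelled with an anatomical
region, profiled for chromatin accessibility, plus region-level RNA-seq
for a three-way contrast (a focal compartment such as the dorsal-pallium
region Dd2, the rest of the pallium D, and the subpallium V). The
pipeline goes from per-sample fragment intervals and peak calls to:

1. a sample quality gate (fragment depth and FRiP),
2. a consensus peak atlas with a normalized accessibility matrix,
3. sample- and peak-level clustering (open chromatin region, OCR,
   clusters) with low-dimensional embeddings,
4. nearest-TSS target genes and genomic context per peak,
5. negative binomial Wald differential expression,
6. "actively regulated" gene sets — genes both differentially expressed
   in a region and targeted by that region's specific OCR clusters,
7. PWM motif enrichment per OCR cluster and positional density
   profiles, and
8. cross-dataset comparisons (shared-motif counts against a foreign OCR
   collection; expression bias of a gene set across a foreign
   region-by-gene expression atlas).

Every stage is exercised end to end on a synthetic cohort generator with
a complete ground-truth record, so the statistical behaviour of each
step is testable without any external download.

## Quality control

A sample passes iff `total_fragments >= min_fragments` **and**
`frip >= min_frip`, both inclusive. Defaults are the standard gate for
this assay: 2 million mapped fragments and FRiP 0.2. FRiP counts a
fragment as in-peak when it overlaps at least 1 bp of at least one of
the *sample's own* peak calls (QC precedes atlas construction), and
counts each fragment once. Samples with zero fragments fail with an
explicit reason rather than dividing by zero.

Design notes: the >= 1 bp overlap rule is the standard interval-overlap
semantics; the field sometimes counts *reads* where we count
*fragments* — the thresholds are arguments precisely so users can match
their upstream counting.

## Atlas construction and normalization

Peak calls of all passing samples are merged transitively: any chain of
pairwise-overlapping peaks collapses to its union, so the atlas is the
connected-overlap closure, non-overlapping and sorted. Counts are
fragments overlapping each atlas peak (>= 1 bp; a fragment spanning the
gap between two atlas peaks is counted in both, which we document rather
than arbitrate). Normalization is depth- then peak-relative:

$$\mathrm{norm}_{ij} = \frac{c_{ij}/T_j}{\frac{1}{m}\sum_{j'} c_{ij'}/T_{j'}}$$

with $c_{ij}$ the fragment count of peak $i$ in sample $j$ and $T_j$ the
sample's *total* mapped fragments. Every retained row has mean exactly 1
across samples; all-zero rows carry no information and are dropped (and
counted). No quantile or variance rescaling is applied beyond this
formula. Note a consequence relevant to interpretation: a peak open in
few samples gets large normalized values in those samples (the row mean
is anchored at 1), so region-specific peaks dominate distances — which
is what makes regional structure visible to the clustering.

## Clustering and embeddings

Samples are clustered on Euclidean distances between normalized columns
with Ward linkage. We use the squared-Euclidean Ward objective
(`ward.D2`); the historical ambiguity of "ward" in R's `hclust` is
resolved to D2 because that is the textbook Ward criterion.

Peaks (OCRs) are clustered with k-means — Lloyd iterations from
k-means++ starts, best of 10 restarts by within-cluster sum of squares,
seeded — with `k = 15` as the default regional OCR classification;
restarts that converge with an empty cluster are re-seeded and counted.
Labels are relabelled by descending cluster size so label 1 is always
the largest cluster, making labels stable across runs. The matrix is
clustered exactly as normalized (no z-scoring), keeping the row-mean-1
anchoring.

Embeddings: PCA (deterministic), t-SNE (default perplexity 5, requiring
`perplexity < (n-1)/3`), UMAP (default `n_neighbors = 7`,
`n_components = 2`), the latter two seeded. The "distinct region"
diagnostic is the mean pairwise embedded distance from each region's
samples to all others.

## Peak annotation

The target gene of a peak is the gene with the nearest TSS, assigned
only when that distance is *strictly* less than 10 kb. Distances are
measured from the peak midpoint: merged atlas peaks carry no summit, so
the midpoint is the only anchor defined for them (nearest-edge is
available as an option). Equidistant ties break to the
lexicographically smaller gene id, for determinism. Genomic context is
classified at the midpoint with precedence promoter > exon > intron >
intergenic; the promoter is the strand-aware 1 kb window upstream of the
TSS (a conventional default — the window is an argument), and genomes
without exon models treat each gene body as a single exon.

## Differential expression

Counts are normalized with median-of-ratios size factors. Each gene gets
a negative binomial GLM with log link and design intercept + group
(equivalently one scaled mean per group), `Var = mu + alpha mu^2`. The
Wald statistic is the log2 fold change over its standard error from the
expected information, referred to a standard normal, two-sided, with
Benjamini–Hochberg adjustment over tested genes; all-zero genes are
excluded from testing and from the BH denominator. Significance is
`padj < 0.05`.

Dispersion estimation is where small designs bite. Per-gene plain ML at
2 + 2 replicates is biased low — genes whose within-group pairs are
tight by chance get `alpha -> 0` and arbitrarily large Wald statistics.
Two corrections are applied, both standard ideas in this model family:

* **Cox–Reid adjustment**: the profile likelihood of `alpha` is
  penalised by $-\tfrac12 \log\det(X^\top W X)$, countering the degrees
  of freedom absorbed by the fitted means.
* **Cohort-median floor**: each gene's estimate is floored at the median
  estimate across genes. The floor is asymmetric on purpose:
  underestimated dispersions inflate type-I error, overestimated ones
  only cost power.

With both, a 2000-gene null simulation (2 vs 2, dispersion 0.05) yields
zero BH rejections and a raw p < 0.05 rate of ~0.065, while planted
|log2FC| = 2 genes at mean 500 are detected with power ~0.96 and median
|LFC error| ~0.22, and fold-change estimates correlate 1.00 with an
independent NB GLM implementation. We deliberately do not shrink fold
changes, apply independent filtering, or handle count outliers; those
belong to heavier toolkits, and the simulations above are the evidence
that the lean estimator is adequate at this scale. The optimizer itself
is a vectorised golden-section search on `log alpha` over
`[1e-8, 50]` (the lower bound doubles as the positivity floor), with the
group means re-profiled by Newton steps at every evaluation.

## Integration: actively regulated genes

The target-gene sets of selected OCR clusters (union over their peaks'
assigned targets) are intersected with the preferentially up- or
down-regulated gene sets (optionally restricted to a category list
supplied as GMT, e.g. synaptic genes). The reported fraction is
`|preferential ∩ targets| / |preferential|`; it is monotone
non-decreasing in the cluster set, and undefined (flagged, not 0) for an
empty universe. "Targeted" means assigned nearest-TSS target of at least
one peak in the cluster — no second distance check is applied beyond the
assignment rule.

## Motif analysis

PWMs carry per-position base probabilities, a background (uniform by
default), and a log-odds threshold defaulting to 80% of the motif's
maximum score — a common operating point when no cutoff is stated.
Scanning scores every window on both strands with
$\sum_j \log_2(p_{j,b}/q_b)$; `N` bases contribute 0 bits; probabilities
are floored at 1e-4 inside the log so impossible bases stay finite.

Enrichment per cluster uses all *other* atlas peaks as background — a
self-contained choice that matches the composition of the atlas rather
than delegating to an external tool's genomic background — and tests
over-representation of hit-bearing peaks with the one-sided
hypergeometric tail; BH across the library is reported alongside. The
`-log10 p > 100` flag mirrors the conventional dot-plot display gate and
is exactly that: a display gate, not a test.

Density profiles count hit starts by offset from the peak centre in a
2000 bp window with 20 bp bins (the conventional histogram settings for
this analysis); peaks truncated by chromosome edges contribute only to
the bins they cover, and each bin is normalised by its covering peak
count, giving hits per peak per bin. Foreign-tool histogram conventions
differ in edge handling; ours is documented rather than claimed
identical.

## Term over-representation

Hypergeometric upper tail per term over a user-chosen universe — by
default all genes tested for differential expression, since that is the
set that had a chance to enter the study set. Terms with fewer than 3
universe genes are not tested (noise guard, configurable). Fold
enrichment is `(k/n)/(K/N)`; `FDR < 0.01` marks the conventional display
gate. No GO-graph ancestor propagation is applied: annotations are taken
as the GMT gives them.

## Cross-dataset comparisons

A foreign region-by-gene expression atlas is normalized per region by
the mean over *all* genes, so every region's all-gene mean is 1; the
regional bias of a gene set is then its per-region mean with a
descriptive score max/median. No test is attached — the score supports a
qualitative claim ("no region stands out"), and attaching a p-value to a
max-statistic over 12 correlated regions would suggest more precision
than the design has. Orthology mapping is a user-supplied two-column
table; foreign ids receiving multiple own genes are dropped, the
standard exclusion for ambiguous orthology. Motif-landscape comparison
delegates to the shared-motif count matrix and per-region density
profiles.

## The synthetic cohort generator

The generator emulates the data structure the pipeline is built for:

* truth peaks partitioned into clusters, placed with enough spacing that
  per-sample jitter (recentring N(0, 20 bp), 5% drop-out) can never fuse
  two truth peaks in the merged atlas — so atlas peaks remain matchable
  to truth for scoring;
* a cluster-to-region activity map, with one "distinct" region holding
  private clusters closed everywhere else;
* fragments of fixed 200 bp length placed inside active peaks with
  probability `frip_target` and uniformly over the genome otherwise —
  the simplest background with a known FRiP expectation;
* planted QC failures by low depth or low in-peak rate;
* NB expression counts with planted fold changes, optionally *coupled*
  to the target genes of chosen peak clusters so the integration stage
  has a known expected fraction;
* PWM consensus instances planted into chosen clusters at a Gaussian
  offset around peak centres.

Sequencing depth per micro-dissected sample is a free scale parameter
(real yields vary by dissection protocol); the simulated cohorts in the
tests and the acceptance script use 5e4–1e5 fragments per sample with a
matching depth gate of 5e4, which keeps binomial FRiP concentration
(±0.05) while running in seconds. The field-standard gate of 2e6
remains the default of `qc_filter` itself. All intervals follow the BED 0-based
half-open convention on disk and Bioconductor 1-based closed convention
in memory, converted by the I/O layer.

What the generator does *not* emulate: read-level artefacts (duplicates,
mapping errors, GC bias), correlated fragment placement within peaks,
dispersion heterogeneity across genes, or realistic motif co-occurrence.
Passing tests therefore demonstrate that the algorithms recover planted
structure under clean assumptions — they do not certify performance on
real libraries with those artefacts.

## Problem sizes and numerical choices

The test-suite cohorts use 9–40 samples, 75–600 truth peaks, genomes of
0.4–6 Mb and 2000-gene expression simulations; chosen so the full suite
documents the statistical claims in a couple of minutes on one core.
Row-mean and column-mean identities are asserted to 1e-12;
hypergeometric tails are compared to direct binomial-coefficient
summation (exact in doubles up to N = 50) at 1e-10 relative; k-means
uses 10 restarts with 100 Lloyd iterations; golden-section dispersion
search runs 35 contractions (interval reduced ~4e-8-fold). Degenerate
inputs fail loudly by design: empty peak input warns and returns an
empty atlas, a zero-total sample is an error at normalization (it should
have failed QC), NaNs in the clustered matrix are reported by cell, and
an empty enrichment target or ORA study outside its universe is an
error.

## Known limitations

* Two-group DE only: no multi-factor designs, likelihood-ratio tests, or
  shrunken fold changes.
* Motif enrichment treats peaks as exchangeable; GC- or
  width-matched backgrounds are not built in (the background set is an
  argument, so callers can supply one).
* The nearest-TSS rule assigns at most one target gene; peaks regulating
  several genes, or genes via contacts beyond 10 kb, are out of reach.
* The `-log10 p > 100` and `FDR < 0.01` gates are display conventions
  inherited from the field's figures, not calibrated decision rules.
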