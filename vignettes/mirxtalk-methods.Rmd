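---
title: "Models and design choices behind mirXtalk"
author: "mirXtalk authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and design choices behind mirXtalk}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(mirXtalk)
```

# Scope and model overview

`mirXtalk` analyzes matched miRNA and mRNA expression across graded tumor
samples (grades II, III, IV) together with a predicted miRNA-target list,
a PPI network and pathway gene sets. Expression is assumed normalized and
log-transformed upstream, with duplicate probes collapsed (the readers
average duplicates by arithmetic mean). Grade II samples act as controls
throughout; the two contrasts are III vs II and IV vs II.

This vignette explains each stage's model and assumptions, the tunable
parameters and their defaults, what the synthetic generator does and does
not emulate, the numerical conventions, and the design choices made where
the methodology left them open.

# Stage models

## Differential calling

Per feature, an unpaired pooled-variance Student's t test compares the
case grade against grade II; Welch's variant is available via
`variant = "welch"` for heteroscedastic data. P-values are adjusted by
Benjamini-Hochberg separately within each (feature kind, contrast)
family, because miRNA and gene calls are reported — and thresholded — as
separate families. Features that are constant and identical in both
groups have an undefined statistic; they are retained with t = 0, p = 1
(and a warning) rather than dropped, so the gene universe entering
enrichment does not shift with degenerate features. The FDR threshold
`alpha` defaults to 0.05.

## Signature miRNA-target pairs

A predicted pair qualifies for a contrast when miRNA and gene are both
significant with opposite directions, and Pearson correlation passes
r ≤ `cutoff` (default −0.4) with the asymptotic-test p < `pMax`
(default 0.05). The two-sided p comes from the t transform
t = r·sqrt((n−2)/(1−r²)). Two conventions were left open by the
methodology and are exposed:

* **Correlation sample set.** Default `sampleSet = "contrast"` computes
  each contrast's correlations over grade II plus that contrast's case
  samples, keeping contrasts self-contained (matching the convention of
  reporting per-contrast pair counts); `"all"` uses every shared sample.
* Constant expression vectors leave r undefined; such pairs report
  r = 0, p = 1 (with a warning) and therefore never pass the filter.

## miRNA-pathway enrichment

For each miRNA and contrast, the inversely correlated target set is
tested against each pathway with the cumulative hypergeometric tail
P(X ≥ m) for X ~ Hypergeometric(N, M, n). Conventions:

* **Universe N.** The default universe passed by the pipeline is the
  genes both measured and annotated to at least one pathway — the
  defensible choice when "genome-wide" is not observable; callers can
  pass all measured genes instead.
* **Tail.** `tail = "ge"` (P(X ≥ m), the standard enrichment convention)
  is the default; `tail = "gt"` (P(X > m)) is offered because summation
  bounds of the cumulative formula are written inconsistently in parts
  of the literature.
* **No multiplicity correction by default.** Edges are thresholded on
  raw p < 0.05, the convention for this network construction; a BH
  option (`adjust = TRUE`) exists but is off by default.

Hub miRNAs are the `ceiling(0.15 · n)` highest-degree miRNAs, and every
miRNA tied with the last included one is also a hub — the inclusive rule
is the deterministic resolution of ties. Degree counts distinct
pathways, not edge records.

## Pathway crosstalk

For pathways i and j, each PPI edge between differential genes a ∈ i,
b ∈ j contributes W = −2(ln P(a) + ln P(b) + ln P(a,b)) (natural
logarithms); the pair weight sums W over qualifying edges, counting each
unordered PPI edge once even when both genes lie in both pathways
(preventing double counting in the unordered sum). Conventions:

* **P(a) with two contrasts.** The weight needs one differential p per
  gene while calling produces one per contrast; the package uses the
  smaller of the two, reading "differentially significant" as the gene's
  best evidence across the progression.
* **P(a,b)** is computed over all analysis samples by default
  (configurable via `samples`), since the crosstalk network is a single
  cross-grade object.
* **Clip floor.** P-values below 1e-300 are clipped there so weights
  stay finite; at that floor one edge contributes at most ~4144 to the
  weight, far above any realistic signal, so clipping cannot mask
  ordering.

Significance comes from gene-set resampling: both pathways'
differential-gene sets are replaced by uniform without-replacement draws
of the same sizes from the pooled significant differential genes
("joint" mode; a single-side mode is available), the weight is
recomputed, and the p-value is the pseudo-count estimator
(r + 1)/(B + 1) — the raw exceedance frequency can return 0, which is
not a valid p-value. Pairs with no qualifying PPI edge have weight 0 and
permutation p exactly 1 (every resampled weight is ≥ 0), so no rounds
are spent on them. `B` defaults to 1000 in the package; full-scale
analyses conventionally use up to 1e6 rounds, and the calibration and
recovery tests use 200-500 because they assert calibration, not
precision.

## Modules

Maximal bicliques of the bipartite network are enumerated by completing
each side internally and running maximal-clique enumeration: the maximal
cliques containing vertices of both sides are exactly the maximal
bicliques. Size floors default to 1×1 so that a single miRNA regulating
several pathways is a representable module. Clique percolation follows
the CFinder construction: k-cliques chained by (k−1)-node overlaps;
k defaults to 3, the smallest nontrivial size, since no k is canonical.
Module identifiers are assigned after lexicographic sorting, making the
numbering deterministic. The core-module extractor returns the
percolation community containing an anchor pathway plus the community's
direct neighbors — the "indirect crosstalk route" pathways.

## Survival stratification

The signature feature matrix (genes, miRNAs, or both) is standardized
per feature before K-means with k = 2 and 10 restarts — without
standardization one expression layer would dominate the Euclidean
distance. The group with the smaller Kaplan-Meier median is labeled
"short" (a never-reached median counts as infinite; the lower-index
group wins exact ties). The median convention is the smallest t with
S(t) ≤ 0.5. Event-time ties use the standard grouped product-limit
formula. Separation is tested by the two-group log-rank statistic
(1 df chi-square); with no events in either group the statistic is
reported as 0 with p = 1 and a warning. Heatmap ordering clusters
samples within each grade by complete linkage on Euclidean distance
(grades kept contiguous in II, III, IV order) and features across all
samples; dendrogram ties resolve to the lower-index leaf.

# The synthetic generator

`syntheticConfig()` defaults describe the emulated study: 63/33/64
samples in grades II/III/IV; 150 miRNAs and 1200 genes of which 40 and
300 are differential (shifted ±2 log-units in grades III and IV —
roughly the differential fraction seen in graded expression studies, at
desk scale); each planted miRNA represses 4 target genes with slope
−0.8 and residual SD 0.5; 25 pathways of 40 genes (so 300 pathway pairs
are scored); background PPI density 0.03 with the planted crosstalk
pairs — the leading clique edges over a small core pathway set — wired
at 5× background among their differential genes; hazard ratio 3 between
risk groups with ~20% censoring and a 28-month low-risk median.

Design notes:

* Expression is drawn directly on log scale (normalization is upstream
  of this package's scope). Feature baselines are N(7, 1) for miRNAs
  and N(8, 1) for genes with unit residual SD.
* Each planted miRNA's targets are placed inside one pathway — the
  planted enrichment ground truth; remaining differential genes are
  spread evenly, and pathways are filled with non-differential genes
  (disjointly unless `allowPathwayOverlap`).
* Decoy predicted pairs are drawn uniformly from non-differential
  features, giving the signature filter measurable specificity.
* Planted crosstalk pairs form the leading edges of a clique over a
  small core pathway set, so clique percolation has a plantable core
  community to recover.
* Survival is exponential per risk group; censoring times are uniform
  on a horizon solved (by `uniroot`) to hit the configured expected
  censoring fraction. Risk groups are fair coin flips tied to an
  expression factor loading on the planted features with separation 3
  log-units (`factorEffect`); the loading exceeds the grade shift so
  that the risk factor, not grade, is the dominant variance axis of the
  signature features — the stratification design requires two-group
  clustering to be able to recover the risk groups. Coupled target
  genes inherit the factor through their miRNA (scaled by the coupling
  slope), direct differential genes carry it explicitly.

What the generator does **not** emulate: batch effects, heavy-tailed or
count-scale expression, correlated decoy targets, scale-free PPI
topology, overlapping pathway annotation (unless enabled), non-
proportional hazards, and real identifier vocabularies. Passing tests
therefore demonstrate the statistical machinery is implemented correctly
and calibrated under a clean generative model — not that the pipeline is
robust to every artifact of real tumor cohorts.

# Determinism and problem sizes

Every stochastic step (generation, permutation, K-means restarts) is
seeded; `runPipeline()` with a fixed configuration and seed produces
byte-identical tables and manifests, with values rounded to 6 decimals
at generation time so files and in-memory objects agree exactly. The
test suite validates the enrichment statistic against exhaustive
enumeration for all universes up to N = 12, the crosstalk weight
against a double-loop oracle on random 16-gene instances, both module
detectors against brute force on graphs of up to 12 vertices, the
permutation null's uniformity on 300 pathway pairs at B = 200, and the
survival chain over 50 replicates of a 60-sample design — sizes chosen
so the whole suite runs in about a minute while keeping Monte-Carlo
error well inside the asserted margins.

# Known limitations

* The crosstalk permutation redraws gene sets but keeps the PPI graph
  and per-gene p-values fixed; strong co-expression blocks inside the
  differential pool can make the null slightly conservative or liberal
  on real data.
* Fisher's method assumes the three combined p-values are independent,
  which correlated expression violates; the permutation null, not the
  nominal chi-square scale of W, carries the inference, which is why no
  parametric p is reported for weights.
* Biclique enumeration is exponential in the worst case; it is intended
  for the sparse bipartite networks this analysis yields, not dense
  graphs with hundreds of vertices per side.
* K-means stratification assumes two roughly balanced expression-defined
  groups; gradual risk continua will split arbitrarily.

# Session info

```{r}
sessionInfo()
```
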