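---
title: "Methods: consensus maps, meta-QTL clustering and synteny-based candidates"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: consensus maps, meta-QTL clustering and synteny-based candidates}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(qtlmeta)
```

## The problem

Dozens of independent quantitative-genetic studies in bread wheat each
report QTLs for yield (GY), grain protein content (GPC) and baking quality
(BQ) on their own genetic maps, with their own marker sets and their own
cM coordinate systems. Individually these QTLs have wide confidence
intervals; collectively, QTLs that co-locate across studies pinpoint the
same underlying locus much more precisely. `qtlmeta` implements the full
integration chain: merge the maps into one consensus coordinate system,
project every QTL into it, combine co-locating QTLs into meta-QTLs
(MQTLs) with pooled confidence intervals, and walk from an MQTL interval
to the ordered gene list beneath it and to alignment-scored candidate
genes.

## Consensus map construction

Maps are merged pairwise onto a backbone (by default the densest map,
which maximizes the number of shared anchor markers). Before a map is
added, `check_order_consistency()` compares it with the running consensus
chromosome by chromosome: the retained shared markers are a
maximum-cardinality subset whose order is identical in both maps (a
longest common monotone subsequence over the shared-marker positions),
and everything else is flagged — order conflicts typically correspond to
genotype-specific inversions or mapping errors, and markers placed on
different chromosomes are flagged separately. Flagged markers are dropped
from the *incoming* map only; the consensus keeps its copy, which also
guarantees the consensus stays internally monotone across successive
merges (shared markers are never re-averaged).

Projection itself is *homothetic*: between two consecutive shared
anchors, a position keeps its relative distance to those anchors
(piecewise-linear interpolation). Design choices where the procedure is
underdetermined:

* **Tied anchors.** Anchors sharing a source position are collapsed to
  one anchor at the mean destination, preserving the strict monotonicity
  the interpolation needs.
* **Extrapolation.** Positions beyond the terminal anchors extend the
  terminal interval's scale factor (scale 1 if that interval is
  degenerate); a linear extension is the least-surprise default and is
  flagged on projected QTLs (`extrapolated_left`/`_right`).
* **Name matching** is exact and case-sensitive; alias resolution across
  genotyping platforms is deliberately out of scope and should happen
  upstream.

With fewer than two consistent shared markers on a chromosome, no frame
exists and that chromosome contributes nothing (logged, never silent).

## QTL projection

A QTL is a peak plus a 95% confidence interval. All three coordinates are
pushed through the same frame; monotonicity of the projection guarantees
the interval still contains the peak. QTLs published without a CI receive
an imputed 95% CI of width 20 cM centred on the peak (configurable,
flagged in `ci_imputed`) — source studies vary in what they report and a
20 cM default is a typical single-study interval width. Frames with fewer
than four anchors are flagged `sparse_anchors` so downstream users can
weigh those projections.

## Meta-QTL clustering

Within a trait class and chromosome, each projected QTL becomes an
observation `x_i` (peak position) with standard deviation
`s_i = CI width / 3.92`, the standard Gaussian 95%-CI convention. For a
candidate number of loci K, the model places positions
`mu_1 < ... < mu_K` and assigns observations to them contiguously in map
order; `fit_k_clusters()` maximizes the weighted Gaussian log-likelihood
over all contiguous partitions exactly, by dynamic programming over
breakpoints (O(n^2 K)). Each cluster's ML position is its
precision-weighted mean and its pooled variance is `1 / sum(1/s_i^2)`, so
the consensus CI provably narrows as supporting QTLs accumulate.

Models K = 1..4 plus the n-model (every QTL its own locus) compete on an
information criterion. The default is a *selection-adjusted* criterion in
the Banfield–Raftery "approximate weight of evidence" style: the model is
charged `2K - 1` parameters (K positions and K - 1 breakpoints), each at
cost `2 (3/2 + log n)`. The adjustment is essential with a hard-partition
likelihood: the fit optimizes over the partition as well as the
positions, so unadjusted AIC — which counts only the K positions — almost
always prefers K + 1 clusters. The effect is easy to reproduce:

```{r aic-overfit}
set.seed(1)
x <- rnorm(18, rep(c(20, 60, 100), each = 6), 2)  # three clear loci
s <- runif(18, 1, 3)
select_model(x, s)$K                   # selection-adjusted default
select_model(x, s, criterion = "AIC")$K  # unadjusted AIC overfits
```

`AIC`, `AICc` and `BIC` remain available for comparison. Ties go to the
smaller K (parsimony). Under the default criterion, simulations with
three true loci at 20/60/100 cM, six QTLs each and `s ~ U(1, 3)` recover
the correct K in ≥ 99% of replicates and the positions within 2 cM in
≈ 99% of recovered clusters (recomputed at run time by
`scripts/acceptance.R`).

When the n-model wins (more than four underlying loci on a linkage
group), or a group exceeds 25 observations, the chromosome is cut at
QTL-free gaps — the connected components of the union of the member CIs,
with touching intervals kept together since a separating region must have
positive length — and each segment is re-analyzed independently
(recursion capped at depth 3 with a warning). Clusters backed by at least
two QTLs from at least two distinct populations are reported as MQTLs;
singleton and single-population clusters go to the audit table, never
silently dropped, so every input QTL is accounted for exactly once.

All cM values are computed at full precision and rounded
half-away-from-zero to two decimals only when written.

## Syntenome anchoring and candidate scoring

The syntenome is an ordered gene list per chromosome; it carries rank
order, not base-pair distances, so genes are placed on the map by linear
interpolation *in ordinal rank* between flanking backbone markers (the
only defensible interpolation given the input), extending the terminal
cM-per-ordinal rate beyond the outermost markers. `genes_in_interval()`
then returns the repertoire under any MQTL confidence interval (closed
interval, cM).

Candidate genes are scored from 12-column BLAST tabular alignments.
Because a query–subject pair may produce many overlapping HSPs, HSPs are
first reduced greedily by descending bitscore, discarding an HSP whose
query span overlaps already-accepted coverage by more than 5% of its own
span — without such a rule the cumulative coverage could exceed 100%.
Over the retained HSPs, CIP (cumulative identity percentage) is total
identities over total aligned columns, and CALP (cumulative
alignment-length percentage) is total aligned columns over query length,
capped at 100 for interpretability. Hits rank CIP-first, then CALP, then
subject id (a deterministic tie-break); default acceptance thresholds are
CIP ≥ 60 and CALP ≥ 70, conventional values for this scoring scheme and
fully configurable.

## What the synthetic generators emulate

The generators produce, from a single seed, every input the pipeline
consumes, with recorded ground truth:

* `simulate_maps()` — a true map with uniformly placed markers, plus
  derived maps that subsample markers, re-scale each chromosome
  monotonically (affine scale drawn from 0.8–1.2, the magnitude of
  map-length differences seen between published wheat maps), jitter
  positions (jitter that would break order is redrawn), and optionally
  reverse short marker runs to mimic genotype-specific inversions.
* `simulate_qtl_studies()` — per-population QTL tables scattered around
  true MQTL positions with configurable detection probability, scatter
  and CI widths (defaults 8–20 cM, typical published interval widths).
* `simulate_syntenome()` — genes interleaved between consecutive markers
  with sequential ordinals and every k-th marker as a backbone anchor.
* `simulate_hsps()` — alignment tables whose planted subject reproduces a
  chosen CIP/CALP up to integer-column rounding, plus lower-identity
  decoys.

These synthetic data reproduce the *geometry* of the integration problem
— coordinate distortion, partial marker sharing, multi-population
scatter, order conflicts — but not everything about real data: marker
sharing between real maps is highly non-uniform along chromosomes,
real QTL position errors are not exactly Gaussian and their published CIs
are computed by heterogeneous methods, segregation distortion and
platform-specific marker name clashes do not occur, and the simulated
gene order has no synteny breaks. Passing the no-noise collapse and
recovery tests therefore validates the machinery and its statistical
operating characteristics, not the biological fidelity of any particular
wheat result.

## Problem sizes and numerical choices

The shipped checks use sizes at which the exact oracles are enumerable
and the statistical rates stable: oracle comparisons at n ≤ 12
observations (all contiguous partitions enumerated for every K), 200
replicates for recovery rates, 1,000 random frames for projection
invariants, 100 queries for alignment-score recovery. Degenerate inputs
are handled explicitly: zero-width CIs are rejected (imputation happens
upstream), tied anchor sources are collapsed before projection, empty
groups are skipped, and an empty HSP set yields "no hit" rather than a
zero-scoring hit.

## Known limitations

* The clustering is hard assignment over ordered observations by design;
  no mixture-model/EM soft assignment is offered.
* Marker identity is by exact name; cross-platform aliasing must be
  resolved upstream.
* The published wheat summary tables shipped as fixtures contain small
  internal inconsistencies (a subgenome total off by one from its own
  rows; a few CI widths 0.01 cM above their printed bounds); the package
  reproduces the arithmetic of the per-row values and does not attempt to
  reconcile the printed totals.
* MQTLs whose member QTLs all derive from one population are reported
  but not promoted; with very few contributing studies this can leave
  real loci unresolved — a property of the evidence, not a bug.
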