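---
title: "Methods of the oncogenic expression atlas pipeline"
author: "oncoatlas"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods of the oncogenic expression atlas pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical models, the synthetic study
design, the numerical conventions and the deliberate design choices behind
`oncoatlas`. The package re-implements a single-cell analysis of cardiac
differentiation from human iPSCs — droplet cell calling, stage discovery,
marker detection, oncogene/TSG trend classification, a stage-profile
co-expression network and single-cell MYC/TP53 co-occurrence — over a
seeded synthetic dataset, because no raw data accession accompanies the
study design the package emulates.

## The synthetic study design

`synthetic_config()` defaults *are* the emulated design: four collection
days (day 0/2/4/10) with 11,281 / 6,466 / 8,650 / 5,968 cells, each cell's
latent stage drawn from the published row-stochastic day-by-stage mixture
(`printed_stage_mixture()`), a 50/50 split between two cell lines, 50,000
ambient droplets per day, and the planted stage-V structure: each stage-V
cell is MYC-high with probability 0.149, and TP53 is forced to zero in 70%
of MYC-high cells.

Counts are negative binomial with mean = (per-stage gene mean) × (per-cell
lognormal size factor) and a dispersion (size = 2) shared across genes —
the simplest model exhibiting the overdispersion the marker test must
tolerate. The size-factor lognormal has meanlog 0 and sdlog 0.2 (a ~20%
depth coefficient of variation, typical of droplet libraries); depth is
deliberately time-point-independent since no per-day depth differences are
part of the design. Ambient droplets receive Poisson totals with mean
1.5% of the smallest per-stage expected cell total, spread over genes
proportionally to the day's expected expression; this keeps the 1st
percentile of real-cell totals an order of magnitude above the 99th
percentile of ambient totals, so the percentile calling rule can be exact.

Three planted signals are drawn as shifted counts, `1 + NB`, so that the
corresponding positivity calls are guaranteed rather than merely likely:
*RPS4Y1* in line-1 cells (a plain NB at mean 5 would be zero in ~8% of
cells and break the exact on/off line signal), MYC in MYC-high cells
(mean 30), and TP53 in MYC-high cells that are *not* silenced. TP53
silencing is a forced zero, not a down-scaling, matching the reading of
"silenced" as an observed zero count.

The default `default_gene_panel()` holds 1,197 genes: 10 stage-marker
spikes per stage (mean 25 in their own stage, 0.25 elsewhere, named after
canonical pluripotency/mesoderm/cardiac genes), 300 oncogenes and 500
TSGs of which 25 are strictly doubling (`continuous_up`) and 15 strictly
halving (`continuous_down`) across stages — including *MALAT1*
(36→576 UMI/cell), *SFRP2* and *DNMT3B* — plus flat housekeeping genes.
Flat profiles are exactly constant, so their true trend class is `other`.

One deliberate addition is the `REST_POOL` aggregate gene: a
low-dispersion pseudo-gene whose stage means equalize the expected total
UMI across stages. A ~1,200-gene panel (kept small so the ~3.6 × 10⁵
unordered co-expression pairs enumerate in seconds) lacks the tens of
thousands of background genes that, in real data, dilute stage-specific
expression. Without the pool, *MALAT1* alone shifts stage-V totals enough
that median normalization systematically displaces *every* flat gene
across stages and the marker test flags most of the panel. The pool
restores the property that a flat gene is null under normalization.

What the generator does **not** emulate: doublets, batch effects,
cell-cycle structure, gene–gene correlation beyond the planted structure,
and read-level artifacts. Passing tests therefore demonstrate that the
pipeline recovers the *designed* statistical structure at the designed
sizes — not that it is robust to everything real droplet data contains.

## Cell calling

With `N` expected cells, `m` is the 99th percentile of the top-`N`
barcode totals and every barcode with total > `m`/10 is called. Two
conventions are fixed because no interpolation rule is part of the quoted
procedure: the percentile is **nearest-rank** on the sorted top-`N`
totals (so integer inputs give integer-exact results), and ties at
exactly `m`/10 are **not** called (strict inequality, as stated). An `N`
larger than the available barcodes is clamped with a warning; an all-zero
matrix is an explicit error.

## Normalization

Every cell is rescaled to the median total UMI, after pooling the called
cells of all time points (a per-time-point switch exists, but pooling
matches normalizing "across the four groups" before per-cell median
scaling). The operation is idempotent and preserves zeros; zero-total
cells are an error naming the offending barcodes.

## Stage discovery

PCA operates on log1p of the median-normalized counts, centered per gene;
the log transform is not part of the quoted procedure but stabilizes the
NB variance and is the field default. The covariance matrix is
accumulated from the sparse matrix, so the dense cells × genes matrix is
never materialized. `M` = 10 components is a config default (no value of
`M` is prescribed).

k-means runs for each candidate `k` in 2..10 with 10 seeded restarts. Two
selection criteria are combined as: mean silhouette width is primary, and
exact ties fall back to the SSE elbow (largest second difference), then
to the smaller `k`. The silhouette is computed on a fixed, seeded
subsample of 2,000 cells because the full pairwise distance matrix is
quadratic in cells; at 32 k cells the subsample standard error of the
mean silhouette is far below the gaps between candidate values.

Clusters are ordered into stages I, II, ... by the mean collection-time
rank of their member cells, ties broken by descending size. This replaces
pseudotime ordering with the study's own observation that the stages
track collection time; it is exact on the synthetic design, where the
day-by-stage mixture is strongly diagonal.

## Marker detection

The differential test is a two-part hurdle likelihood-ratio test of stage
versus rest, chosen as the closest published match to a likelihood-ratio
test for single-cell differential expression: a Bernoulli component on
the detection fraction (raw UMI > 0) and a Gaussian component on
log1p-normalized expression among detected cells, with group means and a
pooled variance. The alternative adds one detection-rate and one mean
parameter, so the statistic is referred to χ² with 2 df. All likelihood
maxima are closed-form; the implementation is vectorized over all genes
and stages via sparse cross-products, and a brute-force numerical
maximization of the same likelihood serves as the test oracle.

Genes detected in fewer than 10% of cells in both groups are reported
untested, avoiding degenerate likelihoods. BH adjustment spans the full
gene × stage family of tested hypotheses ("adjusted" without a stated
scope is read as the widest family), and only up-regulated genes
(positive mean difference on the log1p scale) are flagged. The hurdle
statistic's χ² calibration is approximate in small groups; the suite
checks the *flagging* rate on null data, which BH keeps near zero.

## Cancer-gene trends, tiers and co-occurrence

Stage profiles are arithmetic means of **raw** UMI per cell (UMI/cell),
per gene and stage. `continuous_up`/`continuous_down` require strict
monotonicity of all consecutive stage means — "continuous" contrasts with
transient patterns, so a tie breaks the trend. The expression tiers use
UMI/cell ≥ 1.00 (inclusive — the two published tier statements disagree
on strictness and the inclusive form is adopted) and a final-stage mean
> 10.00.

Positivity is raw UMI ≥ 1: the only convention under which a "silenced"
TSG is an observed zero. Trend significance is a cell-level Spearman rank
correlation between raw counts and the ordinal stage index, with the
normal approximation z = ρ√(n−1); constant expression returns p = 1 by
convention. Co-occurrence restricts to one stage, calls TNNT2/MYC double
positives, and partitions them by TP53 positivity; percentages are
half-up at 1 decimal.

## The co-expression network

The gene universe is the union of detected markers and catalog genes,
restricted to genes expressed (any nonzero stage mean). Spearman's ρ is
computed over the five ordered stage means (average ranks on ties);
constant profiles are excluded rather than assigned ρ = 0. p-values use
the t approximation with |ρ| = 1 mapped to p = 0. This choice is
deliberate and consequential: an exact permutation p on five support
points is bounded below by 1/120 and could never survive BH at q < 0.01
over hundreds of thousands of pairs, so the t approximation is the only
reading under which any edge can be retained. A discreteness consequence
is asserted in the tests: attainable ρ values on five untied points are
spaced 0.1 apart, so ρ > 0.99 retains exactly the concordant
(ρ = 1) pairs — and, conversely, any two genes whose noisy profiles
happen to share a rank order (probability 1/120 per pair) form an edge,
which is why the synthetic network carries thousands of edges. The
positive-only filter ("greater than 0.99") excludes perfect
anti-correlation, configurably.

Two pair-counting conventions coexist: ordered-with-self (n², the
reporting convention under which 1,734 genes give 3,006,756 pairs) and
unordered-no-self (n(n−1)/2, the family over which tests and BH run).

## Rounding and the consistency report

`consistency_report()` recomputes derived published values from printed
primary counts only: composition percentages half-up at 2 decimals, the
MYC⁺ percentage half-up at 1 decimal, read depth to the nearest integer,
and the below-tier-1 oncogene share truncated to a whole percent — the
only convention reproducing the printed 72 from (695−189)/695 = 72.8%.
Half-up rounding (not R's round-half-even) is used everywhere a printed
percentage is reproduced.

## Problem sizes and determinism

The test suite runs most module tests on a one-tenth-scale design
(≈ 3.2 k cells, 3 k ambient droplets per day, ~10 s) and the end-to-end
recovery checks on the full design (32,365 cells, 200 k ambient droplets,
~1.5 min), all under fixed seeds; the acceptance script repeats the
full-scale run at the seed it is given. All randomness flows from the
generator seed and the k-means seed, and a fixed seed reproduces every
output byte-for-byte, including written MTX files.

## Known limitations

* The hurdle LRT's χ² reference is asymptotic; raw p-values in very small
  stages are approximate (the BH-adjusted flags are what the pipeline
  consumes).
* The silhouette is subsampled; for fewer than 2,000 cells it is exact.
* Stage ordering assumes stages track collection time; designs where a
  stage is not time-localized would need pseudotime ordering, which is
  out of scope.
* Catalog-dependent counts (numbers of expressed oncogenes, markers,
  edges, nodes) depend on the catalog and dataset and are not meant to
  reproduce any particular published tally; only the planted structure
  and the in-report arithmetic are asserted.
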