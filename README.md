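# oncoatlas

Single-cell transcriptomes of cardiomyocytes differentiated from human
induced pluripotent stem cells (iPSCs) show expression dynamics that
resemble oncogenesis: oncogenes gaining expression and tumor suppressor
genes (TSGs) losing it as differentiation proceeds, down to single cells
that are MYC-positive while TP53 is silenced. `oncoatlas` re-implements
that "oncogenic expression atlas" analysis as a tested, reusable R
pipeline, exercised end-to-end on a seeded synthetic droplet dataset that
emulates the study design (two iPSC lines, four collection days, five
latent stages, ambient empty droplets, planted cancer-gene trends). It is
aimed at computational biologists who want each analysis step as an
auditable, testable function rather than a point-and-click workflow.

## What the pipeline computes

1. **Droplet cell calling.** With `N` expected cells, the maximum total
   UMI is robustly estimated as `m` = the 99th percentile of the top `N`
   barcode totals (nearest rank); every barcode with total UMI > `m`/10 is
   called a cell.
2. **Cell-line assignment and normalization.** Cells with ≥ 1 raw UMI of
   the Y-chromosome marker *RPS4Y1* are assigned to line 1, the rest to
   line 2; every cell is rescaled to the median library size.
3. **Stage discovery.** PCA of log1p-normalized counts (top *M* = 10
   components), k-means over candidate *k* with the number of clusters
   chosen by mean silhouette (SSE elbow as tiebreak), and clusters ordered
   into stages I–V by the mean collection time of their cells.
4. **Marker detection.** Stage-vs-rest two-part hurdle likelihood-ratio
   test (Bernoulli detection + Gaussian expression among detected cells,
   χ² with 2 df), Benjamini–Hochberg adjusted p < 0.05, up-regulated only.
5. **Cancer-gene trends.** Catalog oncogenes/TSGs are tiered by stage-mean
   expression (UMI/cell ≥ 1.00; final-stage mean > 10.00) and classified
   `continuous_up` / `continuous_down` when the five stage means are
   strictly monotone; a cell-level Spearman rank trend test supplies
   p-values.
6. **Co-expression network.** For the union of markers and catalog genes,
   Spearman's ρ over the five-stage mean profiles; pairs with ρ > 0.99 and
   FDR-adjusted q < 0.01 become edges; degree and shortest-path-length
   distributions summarize the topology.
7. **Single-cell co-occurrence.** Among last-stage cells, TNNT2⁺MYC⁺
   double positives (≥ 1 raw UMI each) are partitioned by TP53 positivity;
   "TP53-silent" means zero TP53 UMI.

A consistency report recomputes every derived published quantity (total
cells, read depth per cell, stage composition percentages, the MYC⁺
percentage, the below-tier oncogene share, the evaluated pair count) from
the printed primary counts alone.

## Worked example

A one-tenth-scale study (≈ 3.2 k cells + 12 k ambient droplets) runs in a
few seconds:

```r
library(oncoatlas)

cfg <- synthetic_config(seed = 7,
                        cells_per_timepoint = c(1128, 647, 865, 597),
                        ambient_per_timepoint = 3000)
res <- run_pipeline(list(synthetic = cfg, staging = list(km_seed = 11)))

res$assignment$chosen_k
#> [1] 5
res$composition$percent
#>        day0  day2  day4  day10
#>   I   99.47  0.35  0.18   0.00
#>   II   0.00 92.25  7.32   0.43
#>   III  0.00  0.00 98.90   1.10
#>   IV   0.00  0.00  0.00 100.00
#>   V    0.00  0.00  0.00 100.00
res$cooccurrence[c("n_marker_pos", "n_double_pos",
                   "pct_double_pos", "pct_tsg_silent")]
#> $n_marker_pos
#> [1] 104
#> $n_double_pos
#> [1] 24
#> $pct_double_pos
#> [1] 23.1
#> $pct_tsg_silent
#> [1] 79.2
subset(res$trends, gene %in% c("MALAT1", "SFRP2", "TP53"))[,
  c("gene", "role", "trend_class", "tier", "max_stage_mean", "trend_p")]
#>       gene     role     trend_class        tier max_stage_mean       trend_p
#> 1   MALAT1 oncogene   continuous_up gt10_stageV    615.1333333  0.000000e+00
#> 306  SFRP2      TSG continuous_down         ge1      8.4920635 5.184823e-273
#> 326   TP53      TSG           other      below1      0.4289813  6.708595e-01
```

The pipeline selects five stages whose composition tracks the collection
days; in the cardiomyocyte stage, 24 of 104 TNNT2⁺ cells (23.1%; the
planted rate is 14.9%, and at the full 1,187-cell stage size the estimate
lands on it) are also MYC⁺ and 79.2% of those have TP53 silenced (planted:
70%). *MALAT1* is recovered as a continuously up-regulated, highly
expressed oncogene and *SFRP2* as a continuously down-regulated TSG, while
*TP53* stays below 1 UMI/cell with no monotone trend.

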