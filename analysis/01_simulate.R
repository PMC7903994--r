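#!/usr/bin/env Rscript
# Generate the synthetic differentiation study at the full design size:
# four collection days, 32,365 cells with the published time-by-stage
# composition, 50k ambient droplets per day, planted cancer-gene trends and
# the stage-V MYC/TP53 co-occurrence structure.
suppressPackageStartupMessages(library(oncoatlas))
dir.create("scratch", showWarnings = FALSE)
dir.create("results", showWarnings = FALSE)

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 1L

cfg <- synthetic_config(seed = seed)
ds <- generate_dataset(cfg)
saveRDS(ds, "scratch/dataset.rds")

n_cells <- tapply(ds$truth$is_cell, ds$truth$time_point, sum)
cat("simulated", sum(ds$truth$is_cell), "cells +",
    sum(!ds$truth$is_cell), "ambient droplets over",
    length(ds$matrices), "time points\n")
jsonlite::write_json(list(
  seed = seed,
  cells_per_timepoint = as.list(n_cells),
  n_genes = nrow(ds$panel$genes),
  planted_up = sum(ds$gene_truth$trend_class == "continuous_up"),
  planted_down = sum(ds$gene_truth$trend_class == "continuous_down")
), "results/simulation_summary.json", auto_unbox = TRUE, pretty = TRUE)
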