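#!/usr/bin/env Rscript
# Call cells per time point with the top-N percentile rule, pool them,
# assign cell lines from RPS4Y1 and normalize every cell to the median
# library size.
suppressPackageStartupMessages(library(oncoatlas))
ds <- readRDS("scratch/dataset.rds")

n_expected <- tapply(ds$truth$is_cell, ds$truth$time_point, sum)
n_expected <- n_expected[names(ds$matrices)]
cells <- pool_called_cells(ds$matrices, n_expected)
cells <- assign_cell_line(cells)
cells <- normalize_to_median(cells)
saveRDS(cells, "scratch/cells.rds")

qc <- qc_summary(cells)
cat(sprintf("called %d cells; on average %.0f genes and %.0f UMI per cell\n",
            qc$total_cells, qc$mean_genes_per_cell, qc$mean_umi_per_cell))
write.table(data.frame(time_point = names(qc$cells_per_timepoint),
                       n_cells = as.vector(qc$cells_per_timepoint),
                       mean_genes_per_cell = qc$mean_genes_per_cell,
                       mean_umi_per_cell = qc$mean_umi_per_cell),
            "results/qc_summary.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
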