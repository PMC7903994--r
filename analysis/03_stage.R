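#!/usr/bin/env Rscript
# Discover differentiation stages: PCA on log1p-normalized counts, k-means
# with silhouette-primary k selection, ordering of clusters into stages by
# collection time, and the composition / correlation summaries.
suppressPackageStartupMessages(library(oncoatlas))
cells <- readRDS("scratch/cells.rds")

seed <- as.integer(commandArgs(trailingOnly = TRUE)[1])
if (is.na(seed)) seed <- 2L

scores <- reduce_pca(cells, n_components_M = 10)
assignment <- select_k_and_cluster(scores, k_candidates = 2:10,
                                   km_seed = seed)
assignment <- order_stages(assignment, cells$cell_table)
cells$cell_table$stage <- assignment$stage
saveRDS(assignment, "scratch/assignment.rds")
saveRDS(cells, "scratch/cells.rds")

cat("chose k =", assignment$chosen_k, "stages\n")
write.table(assignment$diagnostics, "results/stage_diagnostics.tsv",
            sep = "\t", quote = FALSE, row.names = FALSE)
comp <- stage_composition(assignment, cells$cell_table)
cat("stage totals:", paste(comp$stage_totals, collapse = ", "), "\n")
write.table(cbind(stage = rownames(comp$counts), as.data.frame(comp$counts)),
            "results/composition_counts.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
write.table(cbind(stage = rownames(comp$percent), as.data.frame(comp$percent)),
            "results/composition_percent.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
cc <- cluster_correlation(cells, assignment)
write.table(cbind(stage = rownames(cc), as.data.frame(cc)),
            "results/stage_correlation.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
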