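#!/usr/bin/env Rscript
# Detect stage-specific marker genes with the two-part hurdle LRT
# (BH-adjusted p < 0.05, up-regulated only).
suppressPackageStartupMessages(library(oncoatlas))
cells <- readRDS("scratch/cells.rds")
assignment <- readRDS("scratch/assignment.rds")

mk <- detect_markers(cells, assignment)
saveRDS(mk, "scratch/markers.rds")
cat("flagged", length(marker_genes(mk)), "marker genes over",
    assignment$chosen_k, "stages\n")
write.table(mk[mk$is_marker, ], "results/markers.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
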