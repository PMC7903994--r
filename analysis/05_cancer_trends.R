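#!/usr/bin/env Rscript
# Overlap markers with the oncogene/TSG catalogs, classify monotone trends
# and expression tiers of catalog genes, and call the stage-V
# TNNT2+/MYC+/TP53 co-occurrence at single-cell resolution.
suppressPackageStartupMessages(library(oncoatlas))
ds <- readRDS("scratch/dataset.rds")
cells <- readRDS("scratch/cells.rds")
assignment <- readRDS("scratch/assignment.rds")
mk <- readRDS("scratch/markers.rds")

dir <- tempfile(); dir.create(dir)
write.table(ds$catalog$oncogenes, file.path(dir, "oncogenes.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
write.table(ds$catalog$tsgs, file.path(dir, "tsgs.tsv"),
            sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE)
catalog <- load_catalog(file.path(dir, "oncogenes.tsv"),
                        file.path(dir, "tsgs.tsv"))

ov <- overlap_markers(mk, catalog)
cat(nrow(ov), "marker genes carry oncogenic or tumor-suppressive roles\n")
write.table(ov, "results/marker_cancer_overlap.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)

profile <- stage_means(cells, assignment)
saveRDS(profile, "scratch/profile.rds")
trends <- trend_calls(cells, assignment, catalog, profile)
write.table(trends, "results/trend_calls.tsv", sep = "\t", quote = FALSE,
            row.names = FALSE)
up <- subset(trends, trend_class == "continuous_up" & role == "oncogene")
dn <- subset(trends, trend_class == "continuous_down" & role == "TSG")
cat(nrow(up), "oncogenes continuously up;", nrow(dn), "TSGs continuously down\n")
cat(sprintf("top oncogene %s peaks at %.2f UMI/cell (trend p = %.2g)\n",
            up$gene[which.max(up$max_stage_mean)], max(up$max_stage_mean),
            up$trend_p[which.max(up$max_stage_mean)]))

last <- stage_labels(assignment$chosen_k)[assignment$chosen_k]
co <- cooccurrence(cells, assignment, stage = last)
cat(sprintf("stage %s: %d TNNT2+ cells, %d (%.1f%%) also MYC+, of which %d (%.1f%%) have TP53 silenced\n",
            last, co$n_marker_pos, co$n_double_pos, co$pct_double_pos,
            co$n_tsg_silent, co$pct_tsg_silent))
jsonlite::write_json(co[setdiff(names(co), "panel")],
                     "results/cooccurrence.json", auto_unbox = TRUE,
                     pretty = TRUE)
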