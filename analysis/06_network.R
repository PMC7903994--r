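#!/usr/bin/env Rscript
# Build the marker/cancer-gene co-expression network: Spearman correlation
# over the 5-point stage profiles, keep rho > 0.99 with BH FDR < 0.01, and
# summarize the network topology.
suppressPackageStartupMessages(library(oncoatlas))
ds <- readRDS("scratch/dataset.rds")
mk <- readRDS("scratch/markers.rds")
profile <- readRDS("scratch/profile.rds")

dir <- tempfile(); dir.create(dir)
write.table(ds$catalog$oncogenes, file.path(dir, "o.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
write.table(ds$catalog$tsgs, file.path(dir, "t.tsv"), sep = "\t",
            quote = FALSE, row.names = FALSE, col.names = FALSE)
catalog <- load_catalog(file.path(dir, "o.tsv"), file.path(dir, "t.tsv"))

universe <- build_universe(mk, catalog, profile)
cat("universe of", length(universe), "genes ->",
    evaluated_pair_count(universe, "unordered_no_self"),
    "unordered pairs evaluated\n")
edges <- pairwise_spearman(profile, universe)
topo <- network_topology(edges, marker_genes(mk))
cat(topo$n_edges, "edges retained over", topo$n_nodes, "nodes (",
    topo$n_marker_nodes, "marker genes )\n")
write.table(edges, "results/coexpression_edges.tsv", sep = "\t",
            quote = FALSE, row.names = FALSE)
jsonlite::write_json(list(
  n_nodes = topo$n_nodes, n_edges = topo$n_edges,
  n_marker_nodes = topo$n_marker_nodes,
  degree_histogram = as.list(topo$degree_histogram),
  path_length_histogram = as.list(topo$path_length_histogram)
), "results/network_topology.json", auto_unbox = TRUE, pretty = TRUE)
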