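#' Printed primary counts of the emulated study
#'
#' The primary (directly counted) quantities the consistency report derives
#' from: per-day cell counts, total clean reads, per-stage composition
#' counts, the stage-V MYC-positive and TP53-expressing counts, the
#' oncogene expression-tier counts and the co-expression universe size.
#'
#' @return named list of printed primary counts.
#' @export
paper_constants <- function() {
  list(
    cells_per_day = c(day0 = 11281, day2 = 6466, day4 = 8650, day10 = 5968),
    total_clean_reads = 2066741896,
    stage_day_counts = printed_stage_counts(),
    stage_v_cells = 1187,
    myc_pos_cells = 177,
    tp53_expressing_among_double_pos = 53,
    oncogenes_expressed = 695,
    oncogenes_ge_tier1 = 189,
    universe_size = 1734
  )
}

#' Recompute derived published quantities from primary counts
#'
#' Every value is a pure function of [paper_constants()]: total cells (sum
#' of per-day counts), mean read depth per cell (reads / cells, nearest
#' integer), the per-stage dominant-day composition percentage (half-up, 2
#' decimals), the stage-V MYC-positive percentage (half-up, 1 decimal), the
#' below-tier-1 oncogene share (truncated to a whole percent, the printed
#' convention), and the ordered-with-self Spearman pair count (n^2).
#'
#' @param constants list from [paper_constants()].
#' @return data.frame `quantity`, `value`, `formula`; byte-stable across
#'   runs.
#' @export
consistency_report <- function(constants = paper_constants()) {
  ct <- constants$stage_day_counts
  stage_tot <- rowSums(t(ct))           # per-stage totals over days
  comp_pct <- round_half_up(100 * t(ct) / stage_tot, 2)  # stage x day
  total_cells <- sum(constants$cells_per_day)
  rows <- list(
    c("total_cells", total_cells, "sum of per-day cell counts"),
    c("mean_read_depth",
      round(constants$total_clean_reads / total_cells),
      "total clean reads / total cells, nearest integer")
  )
  for (s in rownames(comp_pct)) {
    d <- colnames(comp_pct)[which.max(comp_pct[s, ])]
    rows[[length(rows) + 1]] <- c(
      sprintf("stage_%s_%s_pct", s, d), comp_pct[s, d],
      sprintf("100 * %d / %d, half-up 2dp", ct[d, s], stage_tot[s]))
  }
  rows[[length(rows) + 1]] <- c(
    "stage_V_myc_pos_pct",
    round_half_up(100 * constants$myc_pos_cells / constants$stage_v_cells, 1),
    sprintf("100 * %d / %d, half-up 1dp", constants$myc_pos_cells,
            constants$stage_v_cells))
  rows[[length(rows) + 1]] <- c(
    "oncogene_below_tier1_pct",
    floor(100 * (constants$oncogenes_expressed - constants$oncogenes_ge_tier1) /
            constants$oncogenes_expressed),
    sprintf("100 * (%d - %d) / %d, truncated to whole percent",
            constants$oncogenes_expressed, constants$oncogenes_ge_tier1,
            constants$oncogenes_expressed))
  rows[[length(rows) + 1]] <- c(
    "spearman_pair_count",
    evaluated_pair_count(constants$universe_size, "ordered_with_self"),
    sprintf("%d^2 ordered pairs with self", constants$universe_size))
  data.frame(
    quantity = vapply(rows, `[[`, "", 1),
    value = as.numeric(vapply(rows, `[[`, "", 2)),
    formula = vapply(rows, `[[`, "", 3),
    stringsAsFactors = FALSE
  )
}

#' Run the whole synthetic atlas pipeline end-to-end
#'
#' simulate -> cell calling -> line assignment -> median normalization ->
#' PCA -> k-means staging -> composition/correlation -> markers -> cancer
#' trend calls -> co-expression network -> stage-V co-occurrence. All
#' randomness flows from `cfg$synthetic$seed` (generator) and
#' `cfg$staging$km_seed` (clustering); identical configuration reproduces
#' every output exactly. When `out_dir` is given, each step's result is
#' written there as TSV/JSON (plus an RDS checkpoint), `run_report.json`
#' records the thresholds, seeds and MD5 checksums of the written tables,
#' and `resume = TRUE` reuses existing checkpoints instead of recomputing.
#'
#' @param cfg list with elements `synthetic` ([synthetic_config()]),
#'   `panel` (optional, default [default_gene_panel()]), `staging`
#'   (`n_components_M`, `k_candidates`, `km_seed`, `km_restarts`),
#'   `markers` (`alpha_adjusted`, `min_fraction_expressed`), `trend`
#'   (`expr_tier1`, `expr_tier2`), `network` (`rho_threshold`,
#'   `fdr_threshold`), `cooccurrence` (`stage`, `panel`). Alternatively
#'   `catalog_paths = c(oncogenes, tsgs)` to load catalogs from disk; when
#'   simulation is disabled (`cfg$data_dir`), matrices are read from an
#'   MTX directory tree and `catalog_paths` is required.
#' @param out_dir optional run directory.
#' @param resume reuse existing checkpoints in `out_dir`.
#' @return list with every intermediate: `dataset`, `cells`, `scores`,
#'   `assignment`, `composition`, `correlation`, `markers`, `profile`,
#'   `catalog`, `overlap`, `trends`, `universe`, `edges`, `topology`,
#'   `cooccurrence`, `qc`, `consistency`.
#' @export
run_pipeline <- function(cfg, out_dir = NULL, resume = FALSE) {
  cfg$synthetic <- cfg$synthetic %||% synthetic_config()
  cfg$panel <- cfg$panel %||% default_gene_panel()
  st_cfg <- utils::modifyList(
    list(n_components_M = 10, k_candidates = 2:10, km_seed = 1L,
         km_restarts = 10), cfg$staging %||% list())
  mk_cfg <- utils::modifyList(
    list(alpha_adjusted = 0.05, min_fraction_expressed = 0.1),
    cfg$markers %||% list())
  tr_cfg <- utils::modifyList(list(expr_tier1 = 1, expr_tier2 = 10),
                              cfg$trend %||% list())
  nw_cfg <- utils::modifyList(list(rho_threshold = 0.99, fdr_threshold = 0.01),
                              cfg$network %||% list())
  co_cfg <- utils::modifyList(
    list(stage = NULL, panel = c("TNNT2", "MYC", "TP53")),
    cfg$cooccurrence %||% list())
  if (!is.null(cfg$data_dir) && is.null(cfg$catalog_paths))
    stopf("pipeline config is missing 'catalog' paths (catalog_paths)")

  if (!is.null(out_dir)) dir.create(out_dir, recursive = TRUE,
                                    showWarnings = FALSE)
  step <- function(name, expr) {
    if (!is.null(out_dir)) {
      ck <- file.path(out_dir, paste0(name, ".rds"))
      if (resume && file.exists(ck)) return(readRDS(ck))
      val <- force(expr)
      saveRDS(val, ck)
      return(val)
    }
    force(expr)
  }

  if (!is.null(cfg$data_dir)) {
    dirs <- list.dirs(cfg$data_dir, recursive = FALSE)
    dataset <- list(matrices = lapply(dirs, read_droplet_mtx), truth = NULL)
    names(dataset$matrices) <-
      vapply(dataset$matrices, `[[`, "", "time_point")
  } else {
    dataset <- step("dataset",
                    generate_dataset(cfg$synthetic, cfg$panel))
  }

  cells <- step("cells", {
    n_exp <- cfg$expected_cells_N %||%
      vapply(dataset$matrices, function(m) {
        if (!is.null(dataset$truth))
          sum(dataset$truth$is_cell[dataset$truth$time_point == m$time_point])
        else nrow(m$counts)
      }, 0)
    cm <- pool_called_cells(dataset$matrices, n_exp)
    cm <- assign_cell_line(cm)
    normalize_to_median(cm)
  })
  qc <- qc_summary(cells)

  scores <- step("scores", reduce_pca(cells, st_cfg$n_components_M))
  assignment <- step("assignment", {
    a <- select_k_and_cluster(scores, st_cfg$k_candidates, st_cfg$km_seed,
                              st_cfg$km_restarts)
    order_stages(a, cells$cell_table)
  })
  cells$cell_table$stage <- assignment$stage
  composition <- stage_composition(assignment, cells$cell_table)
  correlation <- cluster_correlation(cells, assignment)

  markers <- step("markers",
                  detect_markers(cells, assignment, mk_cfg$alpha_adjusted,
                                 mk_cfg$min_fraction_expressed))
  profile <- step("profile", stage_means(cells, assignment))

  catalog <- if (!is.null(cfg$catalog_paths)) {
    load_catalog(cfg$catalog_paths[[1]], cfg$catalog_paths[[2]])
  } else {
    tmp_o <- tempfile(fileext = ".tsv"); tmp_t <- tempfile(fileext = ".tsv")
    utils::write.table(dataset$catalog$oncogenes, tmp_o, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    utils::write.table(dataset$catalog$tsgs, tmp_t, sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
    on.exit(unlink(c(tmp_o, tmp_t)), add = TRUE)
    load_catalog(tmp_o, tmp_t)
  }
  overlap <- overlap_markers(markers, catalog)
  trends <- step("trends",
                 trend_calls(cells, assignment, catalog, profile,
                             tr_cfg$expr_tier1, tr_cfg$expr_tier2))

  universe <- build_universe(markers, catalog, profile)
  edges <- step("edges",
                suppressMessages(
                  pairwise_spearman(profile, universe, nw_cfg$rho_threshold,
                                    nw_cfg$fdr_threshold)))
  topology <- network_topology(edges, marker_genes(markers))

  last_stage <- co_cfg$stage %||% stage_labels(assignment$chosen_k)[assignment$chosen_k]
  cooc <- cooccurrence(cells, assignment, last_stage, co_cfg$panel)

  result <- list(dataset = dataset, cells = cells, scores = scores,
                 assignment = assignment, composition = composition,
                 correlation = correlation, markers = markers,
                 profile = profile, catalog = catalog, overlap = overlap,
                 trends = trends, universe = universe, edges = edges,
                 topology = topology, cooccurrence = cooc, qc = qc,
                 consistency = consistency_report())

  if (!is.null(out_dir)) write_run_outputs(result, cfg, st_cfg, mk_cfg,
                                           tr_cfg, nw_cfg, out_dir)
  result
}

write_run_outputs <- function(result, cfg, st_cfg, mk_cfg, tr_cfg, nw_cfg,
                              out_dir) {
  wt <- function(df, name) {
    path <- file.path(out_dir, name)
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    path
  }
  ct <- result$cells$cell_table
  paths <- c(
    wt(ct, "cell_table.tsv"),
    wt(data.frame(barcode = ct$barcode, cluster = result$assignment$cluster,
                  stage = result$assignment$stage), "stage_assignment.tsv"),
    wt(as.data.frame(result$composition$counts), "composition.tsv"),
    wt(as.data.frame(result$correlation), "correlation.tsv"),
    wt(result$markers, "markers.tsv"),
    wt(result$trends, "trend_calls.tsv"),
    wt(result$overlap, "overlap.tsv"),
    wt(as.data.frame(result$edges), "edges.tsv"),
    wt(result$consistency, "consistency.tsv")
  )
  jsonlite::write_json(result$cooccurrence[setdiff(names(result$cooccurrence),
                                                   "panel")],
                       file.path(out_dir, "cooccurrence.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  report <- list(
    seeds = list(synthetic = cfg$synthetic$seed, kmeans = st_cfg$km_seed),
    thresholds = list(marker_alpha = mk_cfg$alpha_adjusted,
                      min_fraction_expressed = mk_cfg$min_fraction_expressed,
                      expr_tier1 = tr_cfg$expr_tier1,
                      expr_tier2 = tr_cfg$expr_tier2,
                      rho_threshold = nw_cfg$rho_threshold,
                      fdr_threshold = nw_cfg$fdr_threshold),
    chosen_k = result$assignment$chosen_k,
    n_cells = nrow(result$cells$counts),
    checksums = as.list(tools::md5sum(paths))
  )
  jsonlite::write_json(report, file.path(out_dir, "run_report.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}
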