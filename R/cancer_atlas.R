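#' Load oncogene / tumor-suppressor catalogs from two-column TSVs
#'
#' Each file holds `symbol TAB role` rows (no header). Symbols are
#' upper-cased and de-duplicated; a symbol present in both files is flagged
#' dual-role.
#'
#' @param oncogene_tsv,tsg_tsv paths to the two catalogs.
#' @return list of class `gene_catalog`: `oncogenes`, `tsgs`, `dual`
#'   (character vectors of symbols).
#' @export
load_catalog <- function(oncogene_tsv, tsg_tsv) {
  read_one <- function(path) {
    lines <- readLines(path)
    parts <- strsplit(lines, "\t", fixed = TRUE)
    bad <- which(lengths(parts) != 2 | vapply(parts, function(p)
      any(!nzchar(p)), TRUE))
    if (length(bad))
      stopf("malformed catalog row in %s at line %d: '%s'",
            path, bad[1], lines[bad[1]])
    unique(toupper(vapply(parts, `[[`, "", 1L)))
  }
  onc <- read_one(oncogene_tsv)
  tsg <- read_one(tsg_tsv)
  structure(list(oncogenes = onc, tsgs = tsg,
                 dual = intersect(onc, tsg)),
            class = "gene_catalog")
}

catalog_role <- function(catalog, symbols) {
  ifelse(symbols %in% catalog$dual, "dual",
         ifelse(symbols %in% catalog$oncogenes, "oncogene",
                ifelse(symbols %in% catalog$tsgs, "TSG", NA_character_)))
}

#' Overlap marker genes with the cancer-gene catalog
#'
#' @param markers a `marker_result` from [detect_markers()].
#' @param catalog a `gene_catalog`.
#' @return data.frame `gene`, `role`, `stages` (comma-joined marker stages),
#'   one row per overlapping gene, alphabetical; zero rows if disjoint.
#' @export
overlap_markers <- function(markers, catalog) {
  mk <- markers[markers$is_marker, , drop = FALSE]
  hits <- sort(intersect(unique(mk$gene),
                         union(catalog$oncogenes, catalog$tsgs)))
  data.frame(
    gene = hits,
    role = catalog_role(catalog, hits),
    stages = vapply(hits, function(g)
      paste(sort(unique(mk$stage[mk$gene == g])), collapse = ","), ""),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Per-stage mean raw UMI profile of every gene
#'
#' Entry (g, s) is the arithmetic mean raw UMI count of gene g over the
#' cells assigned to stage s (units: UMI/cell).
#'
#' @param cells a `cell_matrix`.
#' @param assignment a `stage_assignment` with stages ordered.
#' @return genes x stages numeric matrix (rownames = symbols).
#' @export
stage_means <- function(cells, assignment) {
  st <- assignment$stage
  if (is.null(st)) stopf("order_stages() must be run first")
  labs <- stage_labels(assignment$chosen_k)
  n_per <- table(factor(st, levels = labs))
  if (any(n_per == 0))
    stopf("empty stage: %s", paste(labs[n_per == 0], collapse = ", "))
  Z <- Matrix::sparseMatrix(i = seq_along(st), j = match(st, labs), x = 1,
                            dims = c(length(st), length(labs)))
  prof <- as.matrix(Matrix::crossprod(cells$counts, Z))
  prof <- sweep(prof, 2, as.numeric(n_per), "/")
  dimnames(prof) <- list(cells$genes$symbol, labs)
  prof
}

#' Classify the monotone trend and expression tier of genes
#'
#' A gene is `continuous_up` iff its stage means strictly increase across
#' all consecutive ordered stages, `continuous_down` iff they strictly
#' decrease, otherwise `other` (ties break a trend). The expression tier is
#' `gt10_stageV` if the final-stage mean exceeds `expr_tier2`, else `ge1` if
#' any stage mean reaches `expr_tier1` (inclusive), else `below1`.
#'
#' @param profile genes x stages matrix from [stage_means()].
#' @param genes gene symbols to classify (default: all rows).
#' @param expr_tier1 lower tier threshold, UMI/cell (default 1.00).
#' @param expr_tier2 final-stage high tier threshold (default 10.00).
#' @return data.frame `gene`, `trend_class`, `tier`, `max_stage_mean`,
#'   `expressed` (any stage mean > 0).
#' @export
classify_trend <- function(profile, genes = rownames(profile),
                           expr_tier1 = 1, expr_tier2 = 10) {
  stopifnot(expr_tier1 > 0, expr_tier1 < expr_tier2)
  if (ncol(profile) < 3) stopf("need >= 3 ordered stages")
  miss <- setdiff(genes, rownames(profile))
  if (length(miss)) stopf("unknown gene(s): %s", paste(miss, collapse = ", "))
  p <- profile[genes, , drop = FALSE]
  d <- p[, -1, drop = FALSE] - p[, -ncol(p), drop = FALSE]
  up <- apply(d > 0, 1, all)
  down <- apply(d < 0, 1, all)
  data.frame(
    gene = genes,
    trend_class = ifelse(up, "continuous_up",
                         ifelse(down, "continuous_down", "other")),
    tier = ifelse(p[, ncol(p)] > expr_tier2, "gt10_stageV",
                  ifelse(apply(p >= expr_tier1, 1, any), "ge1", "below1")),
    max_stage_mean = apply(p, 1, max),
    expressed = apply(p > 0, 1, any),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Rank trend test of a gene's expression along ordered stages
#'
#' Two-sided p-value of the Spearman correlation between per-cell raw UMI
#' and the ordinal stage index, under the large-sample normal approximation
#' z = rho * sqrt(n - 1). Constant expression returns p = 1 by convention.
#'
#' @param cells a `cell_matrix`.
#' @param assignment a `stage_assignment` with stages ordered.
#' @param gene gene symbol.
#' @return list: `rho`, `p`, `n`.
#' @export
trend_significance <- function(cells, assignment, gene) {
  j <- match(gene, cells$genes$symbol)
  if (is.na(j)) stopf("unknown gene: %s", gene)
  st <- assignment$stage
  if (is.null(st)) stopf("order_stages() must be run first")
  x <- as.vector(cells$counts[, j])
  s <- match(st, stage_labels(assignment$chosen_k))
  if (length(unique(x)) < 2 || length(unique(s)) < 2)
    return(list(rho = NA_real_, p = 1, n = length(x)))
  rho <- stats::cor(x, s, method = "spearman")
  z <- rho * sqrt(length(x) - 1)
  list(rho = rho, p = min(1, 2 * stats::pnorm(-abs(z))), n = length(x))
}

#' Per-cell positivity call for a gene
#'
#' A cell is positive iff its raw UMI count reaches `positivity_min_umi`
#' (default 1); normalization plays no role.
#'
#' @param cells a `cell_matrix`.
#' @param gene gene symbol.
#' @param positivity_min_umi minimum raw UMI (default 1).
#' @return logical vector, one element per cell.
#' @export
positivity <- function(cells, gene, positivity_min_umi = 1) {
  j <- match(gene, cells$genes$symbol)
  if (is.na(j)) stopf("unknown gene: %s", gene)
  as.vector(cells$counts[, j] >= positivity_min_umi)
}

#' Trend calls for all catalog genes present in the data
#'
#' Combines [classify_trend()] on the stage profile with the cell-level
#' rank trend test of [trend_significance()] for each catalog gene.
#'
#' @param cells a `cell_matrix`.
#' @param assignment a `stage_assignment` with stages ordered.
#' @param catalog a `gene_catalog`.
#' @param profile optional precomputed [stage_means()] matrix.
#' @param expr_tier1,expr_tier2 tier thresholds, see [classify_trend()].
#' @return data.frame `gene`, `role`, `trend_class`, `tier`,
#'   `max_stage_mean`, `expressed`, `trend_rho`, `trend_p`.
#' @export
trend_calls <- function(cells, assignment, catalog, profile = NULL,
                        expr_tier1 = 1, expr_tier2 = 10) {
  if (is.null(profile)) profile <- stage_means(cells, assignment)
  genes <- intersect(union(catalog$oncogenes, catalog$tsgs),
                     cells$genes$symbol)
  cls <- classify_trend(profile, genes, expr_tier1, expr_tier2)
  cls$role <- catalog_role(catalog, cls$gene)

  s <- match(assignment$stage, stage_labels(assignment$chosen_k))
  rs <- rank(s)
  rho <- numeric(length(genes)); pv <- numeric(length(genes))
  idx <- match(genes, cells$genes$symbol)
  chunks <- split(seq_along(idx), ceiling(seq_along(idx) / 200))
  n <- length(s)
  for (ch in chunks) {
    X <- as.matrix(cells$counts[, idx[ch], drop = FALSE])
    for (q in seq_along(ch)) {
      x <- X[, q]
      if (length(unique(x)) < 2) { rho[ch[q]] <- NA; pv[ch[q]] <- 1; next }
      r <- stats::cor(rank(x), rs)
      rho[ch[q]] <- r
      pv[ch[q]] <- min(1, 2 * stats::pnorm(-abs(r) * sqrt(n - 1)))
    }
  }
  cls$trend_rho <- rho
  cls$trend_p <- pv
  cls[, c("gene", "role", "trend_class", "tier", "max_stage_mean",
          "expressed", "trend_rho", "trend_p")]
}

#' Single-cell co-occurrence of a marker/oncogene/TSG panel in one stage
#'
#' Restricts to the cells of `stage`, calls positivity for the cardiomyocyte
#' marker and the oncogene (double-positive = both at or above
#' `positivity_min_umi` raw UMI), and partitions double-positive cells by
#' tumor-suppressor positivity ("silent" = zero raw UMI). Percentages are
#' rounded half-up to 1 decimal.
#'
#' @param cells a `cell_matrix`.
#' @param assignment a `stage_assignment` with stages ordered.
#' @param stage stage label (e.g. `"V"`).
#' @param panel character vector `(marker, oncogene, TSG)`; default
#'   `c("TNNT2", "MYC", "TP53")`.
#' @param positivity_min_umi minimum raw UMI for positivity (default 1).
#' @return list of class `cooccurrence_result` with counts
#'   `n_stage_cells`, `n_marker_pos`, `n_double_pos`, `n_tsg_expressing`,
#'   `n_tsg_silent` and percentages `pct_double_pos` (of marker-positive
#'   cells), `pct_tsg_silent`, `pct_tsg_expressing` (of double-positives).
#' @export
cooccurrence <- function(cells, assignment, stage = "V",
                         panel = c("TNNT2", "MYC", "TP53"),
                         positivity_min_umi = 1) {
  miss <- setdiff(panel, cells$genes$symbol)
  if (length(miss)) stopf("panel gene(s) missing: %s",
                          paste(miss, collapse = ", "))
  st <- assignment$stage
  if (is.null(st)) stopf("order_stages() must be run first")
  if (!stage %in% st) stopf("no cells in stage %s", stage)
  in_stage <- st == stage
  pos <- lapply(panel, function(g)
    positivity(cells, g, positivity_min_umi)[in_stage])
  marker_pos <- pos[[1]]
  double_pos <- pos[[1]] & pos[[2]]
  tsg_expr <- double_pos & pos[[3]]
  pct <- function(num, den) if (den > 0) round_half_up(100 * num / den, 1) else NA_real_
  structure(list(
    stage = stage,
    n_stage_cells = sum(in_stage),
    n_marker_pos = sum(marker_pos),
    n_double_pos = sum(double_pos),
    n_tsg_expressing = sum(tsg_expr),
    n_tsg_silent = sum(double_pos) - sum(tsg_expr),
    pct_double_pos = pct(sum(double_pos), sum(marker_pos)),
    pct_tsg_expressing = pct(sum(tsg_expr), sum(double_pos)),
    pct_tsg_silent = pct(sum(double_pos) - sum(tsg_expr), sum(double_pos)),
    panel = panel
  ), class = "cooccurrence_result")
}
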