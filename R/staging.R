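#' PCA reduction of the normalized expression matrix
#'
#' Projects log1p-transformed median-normalized counts, centered per gene,
#' onto the top M principal components. The covariance is accumulated from
#' the sparse matrix, so the cells-by-genes matrix is never densified.
#'
#' @param cells a `cell_matrix` with `normalized` set.
#' @param n_components_M number of components M (default 10).
#' @return cells x M score matrix with attribute `sdev` (component standard
#'   deviations, non-increasing).
#' @export
reduce_pca <- function(cells, n_components_M = 10) {
  if (is.null(cells$normalized))
    stopf("run normalize_to_median() before reduce_pca()")
  X <- cells$normalized
  X@x <- log1p(X@x)
  n <- nrow(X); G <- ncol(X)
  if (n_components_M >= min(n, G))
    stopf("M (%d) must be < min(cells, genes) = %d", n_components_M, min(n, G))
  mu <- Matrix::colMeans(X)
  cov <- (as.matrix(Matrix::crossprod(X)) - n * tcrossprod(mu)) / (n - 1)
  eig <- eigen(cov, symmetric = TRUE)
  V <- eig$vectors[, seq_len(n_components_M), drop = FALSE]
  scores <- as.matrix(X %*% V) -
    matrix(as.vector(crossprod(mu, V)), n, n_components_M, byrow = TRUE)
  colnames(scores) <- paste0("PC", seq_len(n_components_M))
  rownames(scores) <- cells$cell_table$barcode
  attr(scores, "sdev") <- sqrt(pmax(eig$values[seq_len(n_components_M)], 0))
  scores
}

#' k-means clustering with silhouette-primary k selection
#'
#' Runs seeded k-means (with restarts) for every candidate k, recording the
#' total within-cluster sum of squares (SSE) and the mean silhouette width
#' (computed on a fixed seeded subsample of cells, since the full pairwise
#' distance matrix is quadratic in cells). The chosen k maximizes the mean
#' silhouette; exact ties are broken by the SSE elbow (largest second
#' difference of SSE over candidates), then by the smaller k.
#'
#' @param scores cells x M PCA score matrix.
#' @param k_candidates candidate cluster numbers, all >= 2 (default 2:10).
#' @param km_seed RNG seed for restarts and the silhouette subsample.
#' @param km_restarts number of k-means restarts per candidate (default 10).
#' @param silhouette_cells subsample size for silhouette (default 2000).
#' @return list of class `stage_assignment`: `cluster` (integer per cell),
#'   `chosen_k`, `diagnostics` (data.frame k, sse, silhouette), `stage`
#'   (NULL until [order_stages()]).
#' @export
select_k_and_cluster <- function(scores, k_candidates = 2:10, km_seed = 1L,
                                 km_restarts = 10, silhouette_cells = 2000) {
  if (any(k_candidates < 2)) stopf("all k_candidates must be >= 2")
  n <- nrow(scores)
  if (n <= max(k_candidates))
    stopf("need more cells (%d) than max candidate k (%d)", n, max(k_candidates))
  if (all(apply(scores, 2, function(z) diff(range(z))) == 0))
    stopf("degenerate scores: all cells identical")

  set.seed(km_seed)
  idx <- if (n > silhouette_cells) sample.int(n, silhouette_cells) else seq_len(n)
  dsub <- stats::dist(scores[idx, , drop = FALSE])

  fits <- vector("list", length(k_candidates))
  diag <- data.frame(k = k_candidates, sse = NA_real_, silhouette = NA_real_)
  for (i in seq_along(k_candidates)) {
    k <- k_candidates[i]
    set.seed(km_seed + k)
    # Quick-TRANSfer warnings from Hartigan-Wong on large n are benign
    # (restarts still converge); silence them
    km <- suppressWarnings(
      stats::kmeans(scores, centers = k, nstart = km_restarts,
                    iter.max = 100))
    sil_cl <- km$cluster[idx]
    sil <- if (length(unique(sil_cl)) >= 2)
      mean(cluster::silhouette(sil_cl, dsub)[, "sil_width"])
    else -1
    fits[[i]] <- km
    diag$sse[i] <- km$tot.withinss
    diag$silhouette[i] <- sil
  }
  best_sil <- max(diag$silhouette)
  cand <- which(diag$silhouette >= best_sil - 1e-12)
  if (length(cand) > 1) {
    # SSE elbow: largest second difference over the candidate grid
    d2 <- rep(-Inf, nrow(diag))
    inner <- 2:(nrow(diag) - 1)
    if (length(inner))
      d2[inner] <- diag$sse[inner - 1] - 2 * diag$sse[inner] + diag$sse[inner + 1]
    cand <- cand[order(-d2[cand], diag$k[cand])]
  }
  pick <- cand[1]
  structure(list(cluster = fits[[pick]]$cluster, chosen_k = diag$k[pick],
                 diagnostics = diag, stage = NULL),
            class = "stage_assignment")
}

#' Order clusters into stages by collection time
#'
#' Sorts clusters by the mean collection-time rank of their member cells
#' (day 0 -> rank 1, ..., day 10 -> rank 4); ties are broken by descending
#' cluster size. Labels I, II, ... are assigned in sorted order, replacing
#' pseudotime ordering with the observation that stages track collection
#' time.
#'
#' @param assignment a `stage_assignment` from [select_k_and_cluster()], or
#'   an integer cluster vector.
#' @param cell_table per-cell data.frame with a `time_point` column.
#' @return the `stage_assignment` with `stage` (character per cell, Roman
#'   labels) and `stage_of_cluster` filled in.
#' @export
order_stages <- function(assignment, cell_table) {
  cl <- if (inherits(assignment, "stage_assignment")) assignment$cluster
        else as.integer(assignment)
  if (length(cl) != nrow(cell_table))
    stopf("cluster vector length (%d) != cell_table rows (%d)",
          length(cl), nrow(cell_table))
  tr <- time_point_rank(cell_table$time_point)
  ids <- sort(unique(cl))
  mean_rank <- vapply(ids, function(i) mean(tr[cl == i]), 0)
  size <- vapply(ids, function(i) sum(cl == i), 0L)
  ord <- ids[order(mean_rank, -size)]
  lab <- stage_labels(length(ids))
  stage_of_cluster <- stats::setNames(lab, ord)
  stage <- unname(stage_of_cluster[as.character(cl)])
  if (!inherits(assignment, "stage_assignment"))
    assignment <- structure(list(cluster = cl, chosen_k = length(ids),
                                 diagnostics = NULL, stage = NULL),
                            class = "stage_assignment")
  assignment$stage <- stage
  assignment$stage_of_cluster <- stage_of_cluster
  assignment
}

#' Pearson correlation between stage mean expression profiles
#'
#' Correlates the per-stage mean log1p-normalized expression profiles of all
#' stage pairs (1.00 on the diagonal).
#'
#' @param cells a `cell_matrix` with `normalized` set.
#' @param assignment a `stage_assignment` with stages ordered.
#' @return symmetric stage x stage correlation matrix.
#' @export
cluster_correlation <- function(cells, assignment) {
  st <- assignment$stage
  if (is.null(st)) stopf("order_stages() must be run first")
  labs <- stage_labels(assignment$chosen_k)
  if (any(!labs %in% st)) stopf("stage with 0 cells: %s",
                                paste(setdiff(labs, st), collapse = ", "))
  if (length(labs) < 2) stopf("need >= 2 stages")
  Y <- cells$normalized
  Y@x <- log1p(Y@x)
  Z <- Matrix::sparseMatrix(i = seq_along(st), j = match(st, labs), x = 1,
                            dims = c(length(st), length(labs)))
  prof <- as.matrix(Matrix::crossprod(Y, Z))
  prof <- sweep(prof, 2, table(factor(st, levels = labs)), "/")
  colnames(prof) <- labs
  stats::cor(prof)
}

#' Stage-by-time-point composition table
#'
#' Cross-tabulates stage against collection time point, with row (per-stage)
#' percentages rounded half-up to 2 decimals to match printed composition
#' figures.
#'
#' @param assignment a `stage_assignment` with stages ordered.
#' @param cell_table per-cell data.frame with `time_point`.
#' @return list with `counts` (stage x time matrix), `percent` (same shape),
#'   `stage_totals`.
#' @export
stage_composition <- function(assignment, cell_table) {
  st <- assignment$stage
  if (is.null(st)) stopf("order_stages() must be run first")
  tp <- cell_table$time_point
  tp_lev <- unique(tp)[order(unique(time_point_rank(tp)))]
  tab <- table(factor(st, levels = stage_labels(assignment$chosen_k)),
               factor(tp, levels = tp_lev))
  counts <- unclass(tab)
  totals <- rowSums(counts)
  percent <- round_half_up(100 * counts / totals, 2)
  list(counts = counts, percent = percent, stage_totals = totals)
}
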