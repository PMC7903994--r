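#' Stage-specific marker detection by a two-part hurdle likelihood-ratio test
#'
#' For every gene and stage, tests stage-vs-rest differential expression
#' with a hurdle model: a Bernoulli component on the detection fraction
#' (raw UMI > 0) plus a Gaussian component on log1p median-normalized
#' expression among detected cells (group means, pooled variance). The
#' likelihood-ratio statistic is referred to a chi-squared distribution with
#' 2 degrees of freedom (one extra detection rate, one extra mean), and
#' Benjamini-Hochberg adjustment is applied across the full gene-by-stage
#' family of tested hypotheses. Only up-regulated genes (positive log
#' fold-change on the log1p scale) are flagged as markers.
#'
#' Genes detected in fewer than `min_fraction_expressed` of the cells of
#' both groups are reported untested (`tested = FALSE`, NA p-values) to
#' avoid degenerate likelihoods.
#'
#' @param cells a `cell_matrix` with `normalized` set.
#' @param assignment a `stage_assignment` with stages ordered.
#' @param alpha_adjusted BH-adjusted significance threshold (default 0.05).
#' @param min_fraction_expressed minimum detection fraction in either group
#'   for a gene to be tested (default 0.1).
#' @param top_per_stage optional cap: keep only the top N markers per stage
#'   by adjusted p-value.
#' @return data.frame of class `marker_result`: `gene`, `stage`, `stat`,
#'   `p`, `p_adj`, `lfc`, `tested`, `is_marker`.
#' @export
detect_markers <- function(cells, assignment, alpha_adjusted = 0.05,
                           min_fraction_expressed = 0.1,
                           top_per_stage = NULL) {
  st <- assignment$stage
  if (is.null(st)) stopf("order_stages() must be run first")
  labs <- stage_labels(assignment$chosen_k)
  if (length(labs) < 2) stopf("need >= 2 stages")
  n_per <- table(factor(st, levels = labs))
  if (any(n_per < 2)) stopf("every stage needs >= 2 cells")
  if (is.null(cells$normalized))
    stopf("run normalize_to_median() before detect_markers()")

  Y <- cells$normalized
  Y@x <- log1p(Y@x)
  D <- Y; D@x <- rep(1, length(D@x))       # detection indicator
  Y2 <- Y; Y2@x <- Y2@x^2
  Z <- Matrix::sparseMatrix(i = seq_along(st), j = match(st, labs), x = 1,
                            dims = c(length(st), length(labs)))
  k_gs <- as.matrix(Matrix::crossprod(D, Z))    # detected cells, gene x stage
  s1_gs <- as.matrix(Matrix::crossprod(Y, Z))   # sum y among detected
  s2_gs <- as.matrix(Matrix::crossprod(Y2, Z))  # sum y^2 among detected
  if (any(colSums(k_gs) == 0))
    stopf("stage with all-zero counts for all genes: %s",
          paste(labs[colSums(k_gs) == 0], collapse = ", "))

  k_tot <- rowSums(k_gs); s1_tot <- rowSums(s1_gs); s2_tot <- rowSums(s2_gs)
  n_tot <- length(st)
  G <- nrow(k_gs)

  # Bernoulli log-likelihood at the MLE rate, k successes of n
  ll_bin <- function(k, n) {
    out <- numeric(length(k))
    mid <- k > 0 & k < n
    out[mid] <- k[mid] * log(k[mid] / n[mid]) +
      (n[mid] - k[mid]) * log1p(-k[mid] / n[mid])
    out
  }
  # Gaussian profile log-likelihood given total n, residual sum of squares
  ll_gauss <- function(n, ss) {
    s2 <- pmax(ss / pmax(n, 1), 1e-12)
    ifelse(n > 0, -n / 2 * (log(2 * pi * s2) + 1), 0)
  }
  rss <- function(n, s1, s2) pmax(s2 - ifelse(n > 0, s1^2 / pmax(n, 1), 0), 0)

  res <- vector("list", length(labs))
  for (j in seq_along(labs)) {
    k1 <- k_gs[, j];  s11 <- s1_gs[, j];  s21 <- s2_gs[, j]
    k2 <- k_tot - k1; s12 <- s1_tot - s11; s22 <- s2_tot - s21
    n1 <- as.integer(n_per[j]); n2 <- n_tot - n1

    ll0 <- ll_bin(k1 + k2, rep(n_tot, G)) +
      ll_gauss(k1 + k2, rss(k1 + k2, s11 + s12, s21 + s22))
    ll1 <- ll_bin(k1, rep(n1, G)) + ll_bin(k2, rep(n2, G)) +
      ll_gauss(k1 + k2, rss(k1, s11, s21) + rss(k2, s12, s22))
    stat <- pmax(2 * (ll1 - ll0), 0)
    tested <- (k1 / n1 >= min_fraction_expressed) |
      (k2 / n2 >= min_fraction_expressed)
    p <- ifelse(tested, stats::pchisq(stat, df = 2, lower.tail = FALSE), NA)
    lfc <- s11 / n1 - s12 / n2   # mean log1p expression over all cells
    res[[j]] <- data.frame(gene = rownames(k_gs) %||% cells$genes$symbol,
                           stage = labs[j], stat = stat, p = p,
                           p_adj = NA_real_, lfc = lfc, tested = tested,
                           stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, res)
  out$p_adj[out$tested] <- stats::p.adjust(out$p[out$tested], method = "BH")
  out$is_marker <- !is.na(out$p_adj) & out$p_adj < alpha_adjusted & out$lfc > 0
  if (!is.null(top_per_stage)) {
    keep <- unlist(lapply(split(seq_len(nrow(out)), out$stage), function(i) {
      mk <- i[out$is_marker[i]]
      mk[order(out$p_adj[mk])][seq_len(min(top_per_stage, length(mk)))]
    }))
    out$is_marker <- seq_len(nrow(out)) %in% keep
  }
  rownames(out) <- NULL
  class(out) <- c("marker_result", "data.frame")
  out
}

#' Genes flagged as markers for any stage
#' @param markers a `marker_result`.
#' @return character vector of unique marker gene symbols.
#' @export
marker_genes <- function(markers) unique(markers$gene[markers$is_marker])
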