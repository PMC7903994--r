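#' Gene universe for the co-expression network
#'
#' Union of the detected marker genes and the catalog oncogenes and tumor
#' suppressors, restricted to genes with a nonzero mean in at least one
#' stage, in deterministic (alphabetical) order.
#'
#' @param markers a `marker_result`.
#' @param catalog a `gene_catalog`.
#' @param profile genes x stages matrix from [stage_means()].
#' @return character vector of gene symbols.
#' @export
build_universe <- function(markers, catalog, profile) {
  u <- union(marker_genes(markers), union(catalog$oncogenes, catalog$tsgs))
  u <- intersect(u, rownames(profile))
  u <- u[rowSums(profile[u, , drop = FALSE] > 0) > 0]
  if (!length(u)) stopf("empty gene universe")
  sort(u)
}

#' Number of evaluated expression pairs
#'
#' @param n universe size (or a character universe, whose length is used).
#' @param convention `"ordered_with_self"` (n^2, the reporting convention)
#'   or `"unordered_no_self"` (n(n-1)/2, the testing convention).
#' @return pair count.
#' @export
evaluated_pair_count <- function(n, convention = c("ordered_with_self",
                                                   "unordered_no_self")) {
  if (is.character(n)) n <- length(n)
  switch(match.arg(convention),
         ordered_with_self = n^2,
         unordered_no_self = n * (n - 1) / 2)
}

#' Spearman co-expression edges over stage profiles
#'
#' For every unordered non-self gene pair in the universe, computes the
#' Spearman correlation of the two genes' ordered stage-mean profiles
#' (average ranks on ties), a p-value from the t approximation
#' (|rho| = 1 gives p = 0), and Benjamini-Hochberg adjusted q-values over
#' all pairs. Pairs with rho > `rho_threshold` and q < `fdr_threshold` are
#' retained (one-sided positive filter: perfect anti-correlation is
#' excluded). Constant profile rows have undefined rank correlation and are
#' dropped with a message before pairing.
#'
#' @param profile genes x stages matrix from [stage_means()].
#' @param universe gene symbols to correlate (see [build_universe()]).
#' @param rho_threshold retain rho strictly greater than this (default 0.99).
#' @param fdr_threshold retain BH-adjusted q strictly below this (default
#'   0.01).
#' @param keep `"retained"` (default) returns passing pairs only;
#'   `"all"` returns every evaluated pair with a logical `retained` column.
#' @return data.frame of class `coexpression_edges`: `gene_a < gene_b`,
#'   `rho`, `p`, `q` (and `retained` when `keep = "all"`); attributes
#'   `n_tests`, `n_genes_used`, `dropped_constant`.
#' @export
pairwise_spearman <- function(profile, universe, rho_threshold = 0.99,
                              fdr_threshold = 0.01,
                              keep = c("retained", "all")) {
  keep <- match.arg(keep)
  stopifnot(rho_threshold > 0, rho_threshold < 1,
            fdr_threshold > 0, fdr_threshold < 1)
  ns <- ncol(profile)
  if (ns < 4) stopf("need >= 4 stages for a usable rank correlation")
  P <- profile[universe, , drop = FALSE]
  const <- apply(P, 1, function(v) diff(range(v)) == 0)
  if (any(const)) {
    message(sum(const), " constant profile row(s) excluded: ",
            paste(utils::head(universe[const], 5), collapse = ", "),
            if (sum(const) > 5) ", ...")
    P <- P[!const, , drop = FALSE]
  }
  g <- rownames(P)
  n_g <- length(g)
  if (n_g < 2) stopf("fewer than 2 usable genes in the universe")
  R <- t(apply(P, 1, rank))            # average ranks on ties
  rho <- stats::cor(t(R))
  ut <- upper.tri(rho)
  r <- rho[ut]
  tt <- r * sqrt((ns - 2) / pmax(1 - r^2, 0))
  p <- ifelse(abs(r) >= 1, 0, 2 * stats::pt(-abs(tt), df = ns - 2))
  q <- stats::p.adjust(p, method = "BH")
  ia <- row(rho)[ut]; ib <- col(rho)[ut]
  pass <- r > rho_threshold & q < fdr_threshold
  sel <- if (keep == "all") rep(TRUE, length(r)) else pass
  a <- g[ia[sel]]; b <- g[ib[sel]]
  swap <- a > b
  edges <- data.frame(gene_a = ifelse(swap, b, a),
                      gene_b = ifelse(swap, a, b),
                      rho = r[sel], p = p[sel], q = q[sel],
                      stringsAsFactors = FALSE)
  if (keep == "all") edges$retained <- pass[sel]
  edges <- edges[order(edges$gene_a, edges$gene_b), , drop = FALSE]
  rownames(edges) <- NULL
  attr(edges, "n_tests") <- length(r)
  attr(edges, "n_genes_used") <- n_g
  attr(edges, "dropped_constant") <- sum(const)
  class(edges) <- c("coexpression_edges", "data.frame")
  edges
}

#' Topology summary of the co-expression network
#'
#' Builds the simple undirected graph of retained edges and summarizes the
#' degree distribution and the distribution of shortest path lengths over
#' reachable (connected) node pairs.
#'
#' @param edges a `coexpression_edges` data.frame (may have zero rows).
#' @param marker_genes optional character vector for the marker-node count.
#' @return list of class `network_stats`: `n_nodes`, `n_edges`,
#'   `n_marker_nodes`, `degree_histogram` (named table), `path_length_histogram`.
#' @export
network_topology <- function(edges, marker_genes = NULL) {
  if (nrow(edges) == 0) {
    return(structure(list(n_nodes = 0L, n_edges = 0L, n_marker_nodes = 0L,
                          degree_histogram = table(integer()),
                          path_length_histogram = table(integer())),
                     class = "network_stats"))
  }
  gr <- igraph::graph_from_data_frame(edges[, c("gene_a", "gene_b")],
                                      directed = FALSE)
  gr <- igraph::simplify(gr)
  deg <- igraph::degree(gr)
  dmat <- igraph::distances(gr)
  dd <- dmat[upper.tri(dmat)]
  dd <- dd[is.finite(dd)]
  structure(list(
    n_nodes = igraph::vcount(gr),
    n_edges = igraph::ecount(gr),
    n_marker_nodes = if (is.null(marker_genes)) NA_integer_
                     else sum(igraph::V(gr)$name %in% marker_genes),
    degree_histogram = table(deg),
    path_length_histogram = table(dd)
  ), class = "network_stats")
}
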