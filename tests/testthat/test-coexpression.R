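mk_profile <- function(rows) {
  m <- do.call(rbind, rows)
  colnames(m) <- stage_labels(ncol(m))
  m
}

test_that("the gene universe is the expressed union of markers and catalog", {
  prof <- mk_profile(list(A = c(1, 2, 3, 4, 5), B = c(5, 1, 2, 2, 2),
                          C = c(0, 0, 0, 0, 0)))
  mk <- data.frame(gene = "A", stage = "I", stat = 1, p = 0.01, p_adj = 0.01,
                   lfc = 1, tested = TRUE, is_marker = TRUE)
  cat <- structure(list(oncogenes = "B", tsgs = c("A", "C"),
                        dual = character()), class = "gene_catalog")
  expect_equal(build_universe(mk, cat, prof), c("A", "B"))  # C unexpressed
  # catalog gene absent from the profile is excluded
  cat2 <- structure(list(oncogenes = c("B", "ZZZ"), tsgs = "A",
                         dual = character()), class = "gene_catalog")
  expect_equal(build_universe(mk, cat2, prof), c("A", "B"))
})

test_that("pair counting follows both conventions", {
  expect_equal(evaluated_pair_count(1734, "ordered_with_self"), 3006756)
  expect_equal(evaluated_pair_count(1, "ordered_with_self"), 1)
  expect_equal(evaluated_pair_count(1, "unordered_no_self"), 0)
  expect_equal(evaluated_pair_count(10, "unordered_no_self"), 45)
  expect_equal(evaluated_pair_count(letters[1:10], "unordered_no_self"), 45)
})

test_that("Spearman rho matches the closed form on every 5-value permutation", {
  perms <- as.matrix(expand.grid(rep(list(1:5), 5)))
  perms <- perms[apply(perms, 1, function(r) all(sort(r) == 1:5)), ]
  ref <- c(1.3, 2.7, 3.14, 8, 9.5)   # untied, increasing
  for (i in seq_len(nrow(perms))) {
    x <- c(10, 20, 30, 40, 50)[perms[i, ]]
    prof <- mk_profile(list(A = ref, B = x))
    pair <- pairwise_spearman(prof, c("A", "B"), keep = "all")
    d <- perms[i, ] - 1:5
    rho_closed <- 1 - 6 * sum(d^2) / (5 * (5^2 - 1))
    expect_equal(pair$rho, rho_closed, tolerance = 1e-12)
    # discreteness: exceeding 0.99 is possible only at exact concordance,
    # so retention coincides with rho == 1
    expect_identical(pair$retained, abs(pair$rho - 1) < 1e-12)
  }
})

test_that("edge filtering is one-sided positive at rho > 0.99 and q < 0.01", {
  prof <- mk_profile(list(A = c(1, 2, 3, 4, 5), B = c(10, 20, 30, 40, 50),
                          C = c(5, 4, 3, 2, 1), D = c(2, 1, 5, 3, 4)))
  edges <- pairwise_spearman(prof, rownames(prof))
  expect_equal(nrow(edges), 1)
  expect_equal(c(edges$gene_a, edges$gene_b), c("A", "B"))
  expect_equal(edges$rho, 1)
  expect_equal(edges$p, 0)
  expect_true(all(edges$q >= edges$p))
  # monotone-transform invariance of the retained edge set
  prof2 <- prof; prof2["B", ] <- log(prof["B", ])
  edges2 <- pairwise_spearman(prof2, rownames(prof2))
  expect_identical(edges2[, c("gene_a", "gene_b")],
                   edges[, c("gene_a", "gene_b")])
})

test_that("constant profiles are excluded rather than correlated", {
  prof <- mk_profile(list(A = c(1, 2, 3, 4, 5), K = c(2, 2, 2, 2, 2),
                          B = c(3, 5, 7, 11, 13)))
  expect_message(edges <- pairwise_spearman(prof, rownames(prof)), "constant")
  expect_equal(attr(edges, "n_genes_used"), 2)
  expect_equal(attr(edges, "dropped_constant"), 1)
  expect_equal(nrow(edges), 1)
})

test_that("planted concordant modules become cliques with no cross edges", {
  shape_a <- c(1, 2, 3, 4, 5)
  shape_b <- c(2, 1, 4, 3, 5)   # different rank order: cross rho < 0.99
  rows <- c(lapply(1:10, function(i) i * shape_a),
            lapply(1:10, function(i) (i + 0.5) * shape_b))
  names(rows) <- c(sprintf("A%02d", 1:10), sprintf("B%02d", 1:10))
  prof <- mk_profile(rows)
  edges <- pairwise_spearman(prof, rownames(prof))
  expect_equal(nrow(edges), 2 * choose(10, 2))
  cross <- xor(grepl("^A", edges$gene_a), grepl("^A", edges$gene_b))
  expect_false(any(cross))
  topo <- network_topology(edges)
  expect_equal(topo$n_nodes, 20)
  expect_equal(topo$n_edges, 90)
  expect_true(all(names(topo$degree_histogram) == "9"))
  expect_equal(unname(topo$path_length_histogram["1"]), 90L)
})

test_that("network topology summarizes degrees and shortest paths", {
  tri <- data.frame(gene_a = c("A", "A", "B"), gene_b = c("B", "C", "C"))
  topo <- network_topology(tri)
  expect_equal(topo$n_nodes, 3)
  expect_equal(topo$n_edges, 3)
  expect_equal(sum(as.integer(names(topo$degree_histogram)) *
                     as.vector(topo$degree_histogram)), 2 * topo$n_edges)
  expect_equal(unname(topo$path_length_histogram["1"]), 3L)

  path <- data.frame(gene_a = c("A", "B"), gene_b = c("B", "C"))
  tp <- network_topology(path, marker_genes = c("A", "Z"))
  expect_equal(unname(tp$path_length_histogram["1"]), 2L)
  expect_equal(unname(tp$path_length_histogram["2"]), 1L)
  expect_equal(tp$n_marker_nodes, 1L)

  empty <- network_topology(data.frame(gene_a = character(),
                                       gene_b = character()))
  expect_equal(empty$n_nodes, 0L)
  expect_equal(empty$n_edges, 0L)
})

test_that("degree sum and reachable-pair accounting hold on the synthetic network", {
  res <- scaled_run()
  topo <- res$topology
  expect_equal(sum(as.integer(names(topo$degree_histogram)) *
                     as.vector(topo$degree_histogram)), 2 * topo$n_edges)
  expect_lte(sum(topo$path_length_histogram),
             choose(topo$n_nodes, 2))
  expect_true(all(res$edges$rho > 0.99 & res$edges$q < 0.01))
  expect_true(all(res$edges$gene_a < res$edges$gene_b))
})
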