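norm_cells <- function(counts, ...) normalize_to_median(toy_cells(counts, ...))

test_that("PCA scores capture low-rank structure and report ordered variance", {
  # log-space data lying exactly on a line: a single nonzero component
  cells <- toy_cells(matrix(1, 20, 3))
  cells$normalized <- Matrix::Matrix(expm1(outer(seq(0.1, 2, length.out = 20),
                                                 c(2, 3, 1))), sparse = TRUE)
  sc <- reduce_pca(cells, n_components_M = 2)
  sdev <- attr(sc, "sdev")
  expect_gt(sdev[1], 0)
  expect_lt(sdev[2] / sdev[1], 1e-6)
  expect_error(reduce_pca(cells, n_components_M = 3), "min\\(cells, genes\\)")
})

test_that("sparse-accumulated PCA agrees with dense prcomp", {
  set.seed(5)
  counts <- matrix(rpois(60 * 8, 5), 60, 8)
  cells <- norm_cells(counts)
  sc <- reduce_pca(cells, n_components_M = 4)
  dense <- log1p(as.matrix(cells$normalized))
  pr <- stats::prcomp(dense, center = TRUE, scale. = FALSE)
  expect_equal(attr(sc, "sdev"), pr$sdev[1:4], tolerance = 1e-8)
  for (j in 1:4)
    expect_equal(abs(stats::cor(sc[, j], pr$x[, j])), 1, tolerance = 1e-8)
  # nested projections: captured variance grows with M
  expect_gte(sum(attr(reduce_pca(cells, 3), "sdev")^2),
             sum(attr(reduce_pca(cells, 2), "sdev")^2))
})

test_that("k selection recovers well-separated blobs and is seed-stable", {
  set.seed(9)
  centers <- matrix(c(0, 0, 10, 0, 0, 10, 10, 10, 5, 18), 5, 2, byrow = TRUE)
  lab <- rep(1:5, each = 40)
  scores <- centers[lab, ] + matrix(rnorm(200 * 2, sd = 0.4), 200, 2)
  a1 <- select_k_and_cluster(scores, k_candidates = 2:8, km_seed = 3)
  expect_equal(a1$chosen_k, 5)
  expect_equal(length(unique(paste(a1$cluster, lab))), 5)  # bijection
  a2 <- select_k_and_cluster(scores, k_candidates = 2:8, km_seed = 3)
  expect_identical(a1$cluster, a2$cluster)
  expect_error(select_k_and_cluster(matrix(1, 30, 2), 2:4), "degenerate")
  expect_error(select_k_and_cluster(scores, k_candidates = c(1, 2)), ">= 2")
})

test_that("k-means SSE matches a brute-force multi-start Lloyd search on small instances", {
  set.seed(17)
  pts <- rbind(matrix(rnorm(20, 0, 0.3), 10, 2),
               matrix(rnorm(20, 5, 0.3), 10, 2),
               matrix(rnorm(20, c(0, 8), 0.3), 10, 2))
  a <- select_k_and_cluster(pts, k_candidates = 3, km_seed = 2,
                            km_restarts = 10)
  sse_mod <- a$diagnostics$sse[a$diagnostics$k == 3]

  lloyd <- function(x, centers) {
    for (it in 1:100) {
      d <- as.matrix(stats::dist(rbind(centers, x)))[-(1:nrow(centers)),
                                                     1:nrow(centers)]
      cl <- apply(d, 1, which.min)
      new_c <- apply(x, 2, function(col) tapply(col, factor(cl, 1:nrow(centers)), mean))
      new_c[is.na(new_c)] <- centers[is.na(new_c)]
      if (max(abs(new_c - centers)) < 1e-12) break
      centers <- new_c
    }
    sum((x - centers[cl, ])^2)
  }
  set.seed(31)
  best <- min(vapply(1:60, function(i)
    lloyd(pts, pts[sample(nrow(pts), 3), ]), 0))
  expect_equal(sse_mod, best, tolerance = 1e-9)
})

test_that("stages are ordered by mean collection time, ties by size", {
  # five clusters with majority days (0, 2, 4, 10, 10)
  tp <- c(rep("day0", 30), rep("day2", 30), rep("day4", 30),
          rep("day10", 25), rep("day10", 40))
  cl <- rep(c(3, 5, 1, 2, 4), times = c(30, 30, 30, 25, 40))
  ct <- data.frame(time_point = tp)
  a <- order_stages(cl, ct)
  # cluster 3 (day0) -> I, 5 -> II, 1 -> III; the day-10 pair ties on mean
  # time, so the larger cluster (4, n=40) precedes cluster 2 (n=25)
  expect_equal(unname(a$stage_of_cluster[as.character(c(3, 5, 1, 4, 2))]),
               c("I", "II", "III", "IV", "V"))

  # invariance to cluster-id relabeling
  remap <- c(5, 3, 1, 2, 4)
  a2 <- order_stages(remap[cl], ct)
  expect_identical(a2$stage, a$stage)

  # single cluster gets label I
  one <- order_stages(rep(1, 5), data.frame(time_point = rep("day0", 5)))
  expect_equal(unique(one$stage), "I")
})

test_that("synthetic stages are recovered nearly perfectly after relabeling", {
  res <- scaled_run()
  tr <- res$dataset$truth
  m <- merge(data.frame(barcode = res$cells$cell_table$barcode,
                        stage = res$assignment$stage),
             tr[tr$is_cell, c("barcode", "stage")], by = "barcode")
  tab <- table(m$stage.x, m$stage.y)
  expect_gte(sum(apply(tab, 1, max)) / sum(tab), 0.95)
})

test_that("cluster correlation is a unit-diagonal symmetric Pearson matrix", {
  counts <- rbind(c(10, 0, 5), c(10, 0, 5), c(0, 10, 5), c(0, 10, 5),
                  c(10, 0, 5), c(0, 10, 5))
  cells <- norm_cells(counts)
  a <- toy_assignment(rep(c("I", "II"), 3))
  cc <- cluster_correlation(cells, a)
  expect_equal(diag(cc), c(I = 1, II = 1))
  expect_equal(cc, t(cc), tolerance = 1e-12)
  # stages with identical mean profiles correlate at exactly 1
  counts2 <- rbind(c(10, 0, 5), c(10, 0, 5), c(0, 10, 5), c(0, 10, 5))
  same <- cluster_correlation(norm_cells(counts2),
                              toy_assignment(c("I", "II", "I", "II")))
  expect_equal(same["I", "II"], 1)
  expect_error(cluster_correlation(cells, toy_assignment(rep("I", 6))),
               ">= 2 stages")
})

test_that("stage composition reproduces printed percentages from printed counts", {
  ct <- printed_stage_counts()
  stage <- rep(rep(colnames(ct), 4), as.vector(t(ct)))
  tp <- rep(rownames(ct), rowSums(ct))
  a <- toy_assignment(stage)
  comp <- stage_composition(a, data.frame(time_point = tp))
  expect_equal(unname(comp$stage_totals),
               c(11335, 7041, 8127, 4675, 1187))
  expect_equal(comp$percent["I", "day0"], 99.52)
  expect_equal(comp$percent["I", "day2"], 0.26)
  expect_equal(comp$percent["II", "day2"], 91.42)
  expect_equal(comp$percent["III", "day4"], 98.93)
  expect_equal(comp$percent["IV", "day10"], 99.87)
  expect_equal(comp$percent["V", "day10"], 100.00)
  # row percentages sum to 100 within rounding
  expect_true(all(abs(rowSums(comp$percent) - 100) <= 0.02))

  solo <- stage_composition(toy_assignment(rep("I", 7)),
                            data.frame(time_point = rep("day2", 7)))
  expect_equal(unname(solo$percent["I", "day2"]), 100.00)
})
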