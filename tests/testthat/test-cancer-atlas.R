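write_catalog <- function(symbols, role) {
  path <- tempfile(fileext = ".tsv")
  writeLines(paste(symbols, role, sep = "\t"), path)
  path
}

test_that("catalog loading normalizes case, de-duplicates and flags dual roles", {
  onc <- write_catalog(c("MYC", "myc", "MALAT1"), "oncogene")
  tsg <- write_catalog(c("TP53", "MALAT1"), "TSG")
  cat <- load_catalog(onc, tsg)
  expect_setequal(cat$oncogenes, c("MYC", "MALAT1"))
  expect_setequal(cat$tsgs, c("TP53", "MALAT1"))
  expect_equal(cat$dual, "MALAT1")

  bad <- tempfile()
  writeLines(c("MYC\toncogene", "BROKENROW"), bad)
  expect_error(load_catalog(bad, tsg), "line 2")
})

test_that("written fixture catalogs match the dataset manifest", {
  ds <- generate_dataset(synthetic_config(
    seed = 2, cells_per_timepoint = c(20, 20, 20, 20),
    ambient_per_timepoint = 0))
  dir <- tempfile()
  write_dataset(ds, dir)
  cat <- load_catalog(file.path(dir, "oncogenes.tsv"),
                      file.path(dir, "tsgs.tsv"))
  manifest <- jsonlite::read_json(file.path(dir, "manifest.json"),
                                  simplifyVector = TRUE)
  expect_equal(length(cat$oncogenes), manifest$n_oncogenes)
  expect_equal(length(cat$tsgs), manifest$n_tsgs)
  expect_setequal(union(cat$oncogenes, cat$tsgs), manifest$expressed_union)
})

test_that("marker/catalog overlap has union-intersection semantics", {
  mk <- data.frame(gene = c("A", "B"), stage = "I", stat = 1, p = 0.01,
                   p_adj = 0.01, lfc = 1, tested = TRUE, is_marker = TRUE)
  cat <- structure(list(oncogenes = "B", tsgs = character(), dual = character()),
                   class = "gene_catalog")
  ov <- overlap_markers(mk, cat)
  expect_equal(ov$gene, "B")
  expect_equal(ov$role, "oncogene")

  none <- structure(list(oncogenes = "Z", tsgs = "Y", dual = character()),
                    class = "gene_catalog")
  expect_equal(nrow(overlap_markers(mk, none)), 0)
})

test_that("synthetic overlap contains the planted catalog markers and only true signals", {
  res <- scaled_run()
  ov <- res$overlap
  # catalog entries that are also planted stage spikes must be recovered
  planted_extras <- c("FGF4", "BMP4", "DKK1", "TDGF1", "SOX2", "SOX6", "MEF2C")
  expect_true(all(planted_extras %in% ov$gene))
  # everything in the overlap must be truly differentially expressed:
  # non-constant planted profile, or the co-occurrence-manipulated genes
  panel <- res$dataset$panel
  profile_range <- apply(panel$means[ov$gene, , drop = FALSE], 1,
                         function(v) diff(range(v)))
  truly_de <- profile_range > 0 | ov$gene %in% c("MYC", "TP53")
  # BH at 5% FDR admits a small fraction of flat false discoveries
  expect_lt(mean(!truly_de), 0.15)
})

test_that("stage means equal the brute-force per-stage average of raw counts", {
  set.seed(8)
  counts <- matrix(rpois(10 * 4, 3), 10, 4)
  cells <- toy_cells(counts)
  stage <- rep(c("I", "II"), each = 5)
  prof <- stage_means(cells, toy_assignment(stage))
  for (g in 1:4) for (s in c("I", "II"))
    expect_equal(prof[g, s], mean(counts[stage == s, g]), tolerance = 1e-12)
  # single stage, counts {0, 2, 4} -> mean 2
  one <- stage_means(toy_cells(matrix(c(0, 2, 4), 3)),
                     toy_assignment(rep("I", 3)))
  expect_equal(unname(one[1, "I"]), 2)
})

test_that("trend classification follows strict monotonicity and tier rules", {
  prof <- rbind(UP = c(0.1, 0.5, 1.2, 5, 12),
                FLAT = c(2, 2, 2, 2, 2),
                DOWN = c(4, 3, 2, 1, 0.5),
                LOW = c(0.1, 0.3, 0.2, 0.4, 0.2))
  colnames(prof) <- stage_labels(5)
  cls <- classify_trend(prof)
  expect_equal(cls$trend_class, c("continuous_up", "other",
                                  "continuous_down", "other"))
  expect_equal(cls$tier, c("gt10_stageV", "ge1", "ge1", "below1"))
  expect_error(classify_trend(prof, "MISSING"), "MISSING")

  # scale equivariance: scaling means and tiers together preserves classes
  cls2 <- classify_trend(prof * 7, expr_tier1 = 7, expr_tier2 = 70)
  expect_equal(cls2$trend_class, cls$trend_class)
  expect_equal(cls2$tier, cls$tier)

  # tier1 membership is inclusive: a stage mean of exactly 1.00 counts
  edge <- matrix(c(1, 0.5, 0.5, 0.5, 0.5), 1)
  rownames(edge) <- "EDGE"; colnames(edge) <- stage_labels(5)
  expect_equal(classify_trend(edge)$tier, "ge1")
})

test_that("tier and trend classes partition the expressed catalog genes", {
  res <- scaled_run()
  tr <- res$trends
  expressed <- tr[tr$expressed, ]
  expect_equal(sum(expressed$tier == "below1") +
                 sum(expressed$tier %in% c("ge1", "gt10_stageV")),
               nrow(expressed))
  expect_equal(sum(table(expressed$trend_class)), nrow(expressed))
})

test_that("the rank trend test behaves at its boundaries and on planted trends", {
  counts <- matrix(5, 6, 2)
  colnames(counts) <- c("CONST", "OTHER")
  a <- toy_assignment(rep(c("I", "II", "III"), each = 2))
  expect_equal(trend_significance(toy_cells(counts), a, "CONST")$p, 1)
  expect_error(trend_significance(toy_cells(counts), a, "NOPE"), "NOPE")

  # reversing stage order flips rho, leaves the two-sided p unchanged
  set.seed(3)
  counts2 <- cbind(G = rpois(60, rep(c(1, 4, 9), each = 20)), F = 5)
  cells2 <- toy_cells(counts2)
  fwd <- toy_assignment(rep(c("I", "II", "III"), each = 20))
  rev <- toy_assignment(rep(c("III", "II", "I"), each = 20))
  tf <- trend_significance(cells2, fwd, "G")
  tb <- trend_significance(cells2, rev, "G")
  expect_equal(tf$rho, -tb$rho, tolerance = 1e-12)
  expect_equal(tf$p, tb$p, tolerance = 1e-12)

  # MALAT1-like planted up-trend is overwhelmingly significant
  res <- scaled_run()
  expect_lt(res$trends$trend_p[res$trends$gene == "MALAT1"], 0.001)
  expect_gt(res$trends$trend_rho[res$trends$gene == "MALAT1"], 0)
})

test_that("positivity is a raw-count threshold call", {
  counts <- matrix(c(0, 1, 5), 3, 1)
  colnames(counts) <- "MYC"
  cells <- toy_cells(counts)
  expect_equal(positivity(cells, "MYC"), c(FALSE, TRUE, TRUE))
  expect_equal(positivity(cells, "MYC", positivity_min_umi = 2),
               c(FALSE, FALSE, TRUE))
  expect_error(positivity(cells, "GONE"), "GONE")
  res <- scaled_run()
  tr <- res$dataset$truth
  hi <- tr$barcode[tr$is_cell & !is.na(tr$myc_high) & tr$myc_high]
  pos <- positivity(res$cells, "MYC")
  expect_true(all(pos[res$cells$cell_table$barcode %in% hi]))
})

test_that("co-occurrence counts match a hand tally and are order invariant", {
  #           TNNT2 MYC TP53
  counts <- rbind(c(3, 2, 0),   # double positive, TP53 silent
                  c(5, 0, 1),   # TNNT2+ only
                  c(2, 1, 4),   # double positive, TP53 expressing
                  c(0, 3, 1),   # MYC+ only
                  c(4, 6, 0),   # double positive, TP53 silent
                  c(0, 0, 0))   # triple negative
  colnames(counts) <- c("TNNT2", "MYC", "TP53")
  cells <- toy_cells(counts)
  a <- toy_assignment(rep("I", 6))
  co <- cooccurrence(cells, a, stage = "I")
  expect_equal(co$n_stage_cells, 6)
  expect_equal(co$n_marker_pos, 4)
  expect_equal(co$n_double_pos, 3)
  expect_equal(co$n_tsg_expressing, 1)
  expect_equal(co$n_tsg_silent, 2)
  expect_equal(co$pct_double_pos, 75.0)
  expect_equal(co$pct_tsg_silent, 66.7)

  perm <- c(4, 1, 6, 3, 2, 5)
  co2 <- cooccurrence(toy_cells(counts[perm, ]),
                      toy_assignment(rep("I", 6)), stage = "I")
  expect_equal(co2$n_double_pos, co$n_double_pos)
  expect_equal(co2$n_tsg_silent, co$n_tsg_silent)

  only_tnnt2 <- matrix(rep(c(1, 0, 0), each = 6), 6,
                       dimnames = list(NULL, colnames(counts)))
  none <- toy_cells(only_tnnt2)
  co3 <- cooccurrence(none, a, stage = "I")
  expect_equal(co3$n_double_pos, 0)
  expect_equal(co3$n_tsg_silent, 0)

  expect_error(cooccurrence(cells, a, stage = "I",
                            panel = c("TNNT2", "MYC", "ABSENT")), "ABSENT")
})
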