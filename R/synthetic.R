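#' Published time-point-by-stage composition, as counts
#'
#' Cross-tabulation of the five differentiation stages against the four
#' collection days (day 0, 2, 4, 10) of the study design this package
#' emulates: each row is a collection day, each column an ordered stage.
#'
#' @return integer matrix, 4 time points x 5 stages, dimnames set.
#' @export
printed_stage_counts <- function() {
  m <- rbind(
    day0  = c(11281,    0,    0,    0,    0),
    day2  = c(   29, 6437,    0,    0,    0),
    day4  = c(   23,  581, 8040,    6,    0),
    day10 = c(    2,   23,   87, 4669, 1187)
  )
  colnames(m) <- stage_labels(5)
  m
}

#' Row-stochastic time-point-by-stage mixture of the study design
#'
#' Normalizes [printed_stage_counts()] row-wise, giving the probability that
#' a cell collected at each day belongs to each latent stage. Used as the
#' default `stage_mixture` of [synthetic_config()].
#'
#' @return numeric matrix with rows summing to 1.
#' @export
printed_stage_mixture <- function() {
  m <- printed_stage_counts()
  sweep(m, 1, rowSums(m), "/")
}

#' Default synthetic gene panel
#'
#' A fixed panel of 1197 genes with per-stage mean expression (UMI/cell at
#' unit depth) over the five latent stages:
#' \itemize{
#'   \item 50 stage markers (10 per stage; mean 25 in their own stage, 0.25
#'     elsewhere), named after canonical pluripotency, mesoderm, cardiac
#'     progenitor and cardiomyocyte genes (SOX2, T, GATA4, TNNT2, ...);
#'   \item RPS4Y1 as Y-chromosome sex marker (mean 5, cell line 1 only);
#'   \item 300 oncogenes: MALAT1 and 14 synthetic genes with strictly
#'     doubling stage means (continuous up), 5 with halving means
#'     (continuous down), MYC at a low flat baseline (its stage-V burst is
#'     planted per cell, not per gene), the rest flat;
#'   \item 500 tumor suppressors: SFRP2 and DNMT3B plus 8 synthetic genes
#'     continuously down, 10 continuously up, TP53 at a low flat baseline,
#'     the rest flat;
#'   \item 345 flat housekeeping genes spanning 0.1--5 UMI/cell;
#'   \item one aggregate remainder pool (`REST_POOL`, low dispersion) whose
#'     stage means equalize the expected total UMI across stages, standing
#'     in for the rest of a genome-wide transcriptome.
#' }
#' Flat profiles are exactly constant, so their true trend class is "other"
#' (strict monotonicity is broken by ties).
#'
#' @return list of class `gene_panel` with elements `genes` (data.frame:
#'   `id`, `symbol`, `role`, `trend_class`, `marker_stage`) and `means`
#'   (genes x 5 stages numeric matrix, rownames = symbols).
#' @export
default_gene_panel <- function() {
  up5 <- function(base) outer(base, 2^(0:4))     # strictly increasing
  down5 <- function(base) outer(base, 2^-(0:4))  # strictly decreasing
  flat5 <- function(mu) outer(mu, rep(1, 5))

  marker_sets <- list(
    c("SOX2", "NANOG", "POU5F1", "TDGF1", "PODXL",
      "LIN28A", "DPPA4", "ZFP42", "L1TD1", "USP44"),
    c("T", "MIXL1", "EOMES", "GSC", "DKK1",
      "DKK4", "HES7", "FGF4", "MESP1", "WNT3A"),
    c("GATA4", "NKX2-5", "CCBE1", "BMP4", "ISL1",
      "TBX5", "MEF2C", "HAND1", "SOX6", "ERBB4"),
    c("HAND2", "TNNC1", "MYH6", "TTN", "PLN",
      "MYOM1", "WNT2", "NPPA", "ACTC1", "MYL4"),
    c("TNNT2", "MYH7", "MYOZ2", "ACTN2", "TNNI3",
      "MYL7", "DES", "TNN", "NEXN", "CSRP3")
  )

  blocks <- list()
  add <- function(symbol, role, trend_class, means, marker_stage = NA_integer_) {
    blocks[[length(blocks) + 1L]] <<- list(
      df = data.frame(symbol = symbol, role = role, trend_class = trend_class,
                      marker_stage = marker_stage, stringsAsFactors = FALSE),
      means = means
    )
  }

  for (s in 1:5) {
    mm <- flat5(rep(0.25, 10))
    mm[, s] <- 25
    add(marker_sets[[s]], "stage_marker", "other", mm, marker_stage = s)
  }
  add("RPS4Y1", "sex_marker", "other", flat5(5))

  add("MALAT1", "oncogene", "continuous_up", up5(36))
  add(sprintf("ONCUP%02d", 1:14), "oncogene", "continuous_up",
      up5(seq(0.2, 1.6, length.out = 14)))
  add(sprintf("ONCDN%02d", 1:5), "oncogene", "continuous_down",
      down5(seq(2, 8, length.out = 5)))
  add("MYC", "oncogene", "other", flat5(0.01))
  add(sprintf("ONC%03d", 1:279), "oncogene", "other",
      flat5(seq(0.05, 2, length.out = 279)))

  add("SFRP2", "TSG", "continuous_down", down5(8))
  add("DNMT3B", "TSG", "continuous_down", down5(6))
  add(sprintf("TSGDN%02d", 1:8), "TSG", "continuous_down",
      down5(seq(1, 6, length.out = 8)))
  add(sprintf("TSGUP%02d", 1:10), "TSG", "continuous_up",
      up5(seq(0.2, 1.2, length.out = 10)))
  add("TP53", "TSG", "other", flat5(0.4))
  add(sprintf("TSG%03d", 1:479), "TSG", "other",
      flat5(seq(0.04, 1.8, length.out = 479)))

  add(sprintf("HK%03d", 1:345), "housekeeping", "other",
      flat5(exp(seq(log(0.1), log(5), length.out = 345))))

  # Aggregate remainder pool: one low-dispersion pseudo-gene whose stage
  # means absorb the deficit to the largest stage total, so expected totals
  # are equal across stages. It stands in for the bulk of the transcriptome
  # a genome-wide panel would carry, which dilutes the compositional shift
  # that stage-specific expression would otherwise impose on median
  # normalization.
  tot <- colSums(do.call(rbind, lapply(blocks, `[[`, "means")))
  rest <- max(tot) - tot + 50
  dr <- diff(rest)
  rest_class <- if (all(dr > 0)) "continuous_up"
                else if (all(dr < 0)) "continuous_down" else "other"
  add("REST_POOL", "aggregate", rest_class, matrix(rest, nrow = 1))

  genes <- do.call(rbind, lapply(blocks, `[[`, "df"))
  means <- do.call(rbind, lapply(blocks, `[[`, "means"))
  stopifnot(!anyDuplicated(genes$symbol))
  genes$id <- sprintf("GID%04d", seq_len(nrow(genes)))
  # per-gene NB size: NA = use the shared config dispersion; the aggregate
  # pool of many genes is far less dispersed than any single gene
  genes$nb_size <- ifelse(genes$symbol == "REST_POOL", 50, NA_real_)
  genes <- genes[, c("id", "symbol", "role", "trend_class", "marker_stage",
                     "nb_size")]
  rownames(means) <- genes$symbol
  colnames(means) <- stage_labels(5)
  rownames(genes) <- NULL
  structure(list(genes = genes, means = means), class = "gene_panel")
}

#' Configuration of the synthetic differentiation experiment
#'
#' Defaults reproduce the emulated study design: four collection days with
#' 11281/6466/8650/5968 cells, the published time-by-stage composition,
#' two cell lines split 50/50 and distinguished by RPS4Y1, 50,000 ambient
#' (empty) droplets per day, and the planted stage-V co-occurrence structure
#' (14.9% of cells MYC-high; TP53 forced to zero in 70% of MYC-high cells).
#'
#' @param seed integer RNG seed; the same seed reproduces the dataset
#'   byte-for-byte.
#' @param stage_mixture row-stochastic time x stage matrix.
#' @param cells_per_timepoint integer vector of real cells per collection day.
#' @param ambient_per_timepoint empty droplets added per day.
#' @param depth_lognormal `c(meanlog, sdlog)` of the per-cell library-size
#'   factor.
#' @param nb_dispersion negative-binomial size (shape) shared by all genes.
#' @param line1_fraction probability a cell derives from the RPS4Y1-positive
#'   line.
#' @param frac_myc_pos probability a stage-V cell is MYC-high.
#' @param frac_tp53_silent probability TP53 is forced to zero in a MYC-high
#'   cell.
#' @param myc_high_mean mean raw MYC UMI in MYC-high cells (drawn as
#'   1 + NB so planted cells are always MYC-positive).
#' @param tp53_expressing_mean extra mean TP53 UMI (beyond the guaranteed 1)
#'   in MYC-high cells that are not silenced.
#' @param ambient_rel_umi expected ambient droplet total UMI as a fraction of
#'   the smallest per-stage expected cell total (default 0.015, i.e. well
#'   under 2% of the median real-cell total).
#' @return validated list of class `synthetic_config`.
#' @export
synthetic_config <- function(seed = 1L,
                             stage_mixture = printed_stage_mixture(),
                             cells_per_timepoint = c(11281L, 6466L, 8650L, 5968L),
                             ambient_per_timepoint = 50000L,
                             depth_lognormal = c(meanlog = 0, sdlog = 0.2),
                             nb_dispersion = 2,
                             line1_fraction = 0.5,
                             frac_myc_pos = 0.149,
                             frac_tp53_silent = 0.70,
                             myc_high_mean = 30,
                             tp53_expressing_mean = 1,
                             ambient_rel_umi = 0.015) {
  cfg <- list(
    seed = as.integer(seed), stage_mixture = as.matrix(stage_mixture),
    n_time_points = nrow(stage_mixture),
    cells_per_timepoint = as.integer(cells_per_timepoint),
    ambient_per_timepoint = as.integer(ambient_per_timepoint),
    depth_lognormal = depth_lognormal, nb_dispersion = nb_dispersion,
    line1_fraction = line1_fraction, frac_myc_pos = frac_myc_pos,
    frac_tp53_silent = frac_tp53_silent, myc_high_mean = myc_high_mean,
    tp53_expressing_mean = tp53_expressing_mean,
    ambient_rel_umi = ambient_rel_umi
  )
  class(cfg) <- "synthetic_config"
  validate_synthetic_config(cfg)
  cfg
}

validate_synthetic_config <- function(cfg) {
  mx <- cfg$stage_mixture
  if (any(abs(rowSums(mx) - 1) > 1e-9))
    stopf("stage_mixture rows must sum to 1 (max deviation %.3g)",
          max(abs(rowSums(mx) - 1)))
  if (any(mx < 0 | mx > 1)) stopf("stage_mixture entries must lie in [0, 1]")
  if (length(cfg$cells_per_timepoint) != nrow(mx))
    stopf("cells_per_timepoint length (%d) != stage_mixture rows (%d)",
          length(cfg$cells_per_timepoint), nrow(mx))
  if (any(cfg$cells_per_timepoint <= 0L))
    stopf("cells_per_timepoint must be strictly positive")
  if (cfg$ambient_per_timepoint < 0L)
    stopf("ambient_per_timepoint must be >= 0")
  probs <- c(cfg$line1_fraction, cfg$frac_myc_pos, cfg$frac_tp53_silent)
  if (any(probs < 0 | probs > 1)) stopf("probabilities must lie in [0, 1]")
  if (cfg$nb_dispersion <= 0) stopf("nb_dispersion must be > 0")
  invisible(cfg)
}

random_barcodes <- function(n, width = 16L) {
  draw <- function(k) {
    m <- matrix(sample(c("A", "C", "G", "T"), k * width, replace = TRUE),
                nrow = k)
    paste0(do.call(paste0, as.data.frame(m, stringsAsFactors = FALSE)), "-1")
  }
  bc <- draw(n)
  while (anyDuplicated(bc)) {
    dup <- which(duplicated(bc))
    bc[dup] <- draw(length(dup))
  }
  bc
}

#' Generate the seeded synthetic droplet dataset
#'
#' Emulates the study design end-to-end: for each collection day, draws each
#' cell's latent stage from the day's mixture row, a cell line, and a
#' lognormal library-size factor; gene counts are negative binomial with
#' mean = stage profile x size factor and a shared dispersion. RPS4Y1 counts
#' are zeroed in line-2 cells. In stage-V cells the MYC/TP53 co-occurrence
#' structure is planted per cell: MYC-high cells (probability
#' `frac_myc_pos`) receive `1 + NB` MYC counts, and within them TP53 is
#' forced to zero with probability `frac_tp53_silent` or guaranteed
#' detected (`1 + NB`) otherwise. Ambient droplets get Poisson totals
#' (mean far below real-cell totals) spread over genes proportionally to
#' the day's expected expression, and are shuffled among the real cells.
#'
#' @param config a [synthetic_config()].
#' @param panel a [default_gene_panel()] (or compatible `gene_panel`).
#' @return list of class `synthetic_dataset`: `matrices` (one
#'   `raw_droplet_matrix` per time point), `truth` (per-barcode data.frame:
#'   `barcode`, `time_point`, `is_cell`, `stage`, `cell_line`, `myc_high`,
#'   `tp53_silent`), `gene_truth`, `catalog` (oncogene/TSG data.frames),
#'   `config`, `panel`.
#' @export
generate_dataset <- function(config = synthetic_config(),
                             panel = default_gene_panel()) {
  validate_synthetic_config(config)
  means <- panel$means
  K <- ncol(config$stage_mixture)
  if (ncol(means) != K)
    stopf("panel stage profiles have %d stages but stage_mixture has %d columns",
          ncol(means), K)
  G <- nrow(means)
  genes_df <- data.frame(id = panel$genes$id, symbol = panel$genes$symbol,
                         stringsAsFactors = FALSE)
  i_sex <- match("RPS4Y1", panel$genes$symbol)
  i_myc <- match("MYC", panel$genes$symbol)
  i_tp53 <- match("TP53", panel$genes$symbol)
  tps <- rownames(config$stage_mixture) %||% paste0("t", seq_len(config$n_time_points))
  mu_log <- config$depth_lognormal[[1]]; sd_log <- config$depth_lognormal[[2]]
  disp <- config$nb_dispersion
  size_g <- panel$genes$nb_size %||% rep(NA_real_, G)
  size_g <- ifelse(is.na(size_g), disp, size_g)
  ambient_lambda <- config$ambient_rel_umi * min(colSums(means))

  set.seed(config$seed)
  matrices <- vector("list", config$n_time_points)
  names(matrices) <- tps
  truth <- vector("list", config$n_time_points)

  for (t in seq_len(config$n_time_points)) {
    n <- config$cells_per_timepoint[t]
    stage <- sample.int(K, n, replace = TRUE, prob = config$stage_mixture[t, ])
    line1 <- stats::runif(n) < config$line1_fraction
    depth <- stats::rlnorm(n, mu_log, sd_log)

    mu <- means[, stage, drop = FALSE] * rep(depth, each = G)
    cnt <- matrix(stats::rnbinom(G * n, size = size_g, mu = as.vector(mu)),
                  nrow = G)
    if (!is.na(i_sex)) {
      # exact on/off line signal: line-1 cells always carry >= 1 UMI
      cnt[i_sex, line1] <- 1L + stats::rnbinom(
        sum(line1), size = disp, mu = (means[i_sex, 1] - 1) * depth[line1])
      cnt[i_sex, !line1] <- 0L
    }

    myc_high <- rep(FALSE, n); tp53_silent <- rep(FALSE, n)
    in5 <- which(stage == K)
    if (length(in5) && !is.na(i_myc)) {
      hi <- in5[stats::runif(length(in5)) < config$frac_myc_pos]
      myc_high[hi] <- TRUE
      if (length(hi)) {
        cnt[i_myc, hi] <- 1L + stats::rnbinom(
          length(hi), size = disp,
          mu = pmax(config$myc_high_mean - 1, 0) * depth[hi])
        if (!is.na(i_tp53)) {
          sil <- stats::runif(length(hi)) < config$frac_tp53_silent
          tp53_silent[hi[sil]] <- TRUE
          cnt[i_tp53, hi[sil]] <- 0L
          keep <- hi[!sil]
          cnt[i_tp53, keep] <- 1L + stats::rnbinom(
            length(keep), size = disp,
            mu = config$tp53_expressing_mean * depth[keep])
        }
      }
    }
    cells <- methods::as(Matrix::Matrix(cnt, sparse = TRUE), "CsparseMatrix")

    n_a <- config$ambient_per_timepoint
    if (n_a > 0L) {
      tot_a <- stats::rpois(n_a, ambient_lambda)
      p_gene <- as.vector(means %*% config$stage_mixture[t, ])
      gi <- sample.int(G, sum(tot_a), replace = TRUE, prob = p_gene)
      amb <- Matrix::sparseMatrix(i = gi, j = rep.int(seq_len(n_a), tot_a),
                                  x = 1, dims = c(G, n_a), repr = "C")
      full <- cbind(cells, amb)
    } else {
      full <- cells
    }
    n_all <- n + n_a
    perm <- sample.int(n_all)
    full <- full[, perm, drop = FALSE]
    bc <- random_barcodes(n_all)

    tt <- data.frame(
      barcode = bc, time_point = tps[t],
      is_cell = c(rep(TRUE, n), rep(FALSE, n_a))[perm],
      stage = c(stage_labels(K)[stage], rep(NA_character_, n_a))[perm],
      cell_line = c(ifelse(line1, "line1", "line2"), rep(NA, n_a))[perm],
      myc_high = c(myc_high, rep(NA, n_a))[perm],
      tp53_silent = c(tp53_silent, rep(NA, n_a))[perm],
      stringsAsFactors = FALSE
    )
    matrices[[t]] <- raw_droplet_matrix(Matrix::t(full), bc, genes_df, tps[t])
    truth[[t]] <- tt
  }

  catalog <- panel_catalog(panel)
  out <- list(
    matrices = matrices,
    truth = do.call(rbind, truth),
    gene_truth = panel$genes[, c("symbol", "role", "trend_class")],
    catalog = catalog,
    config = config,
    panel = panel
  )
  class(out) <- "synthetic_dataset"
  out
}

# Catalog TSV content: all panel oncogene/TSG role genes, plus a handful of
# stage markers that real cancer-gene databases also list, so the
# marker/catalog overlap step has a non-trivial planted intersection.
panel_catalog <- function(panel) {
  g <- panel$genes
  onc_extra <- intersect(c("FGF4", "BMP4", "DKK1", "TDGF1", "SOX2"), g$symbol)
  tsg_extra <- intersect(c("DKK1", "SOX6", "MEF2C"), g$symbol)
  list(
    oncogenes = data.frame(
      symbol = c(g$symbol[g$role == "oncogene"], onc_extra),
      role = "oncogene", stringsAsFactors = FALSE),
    tsgs = data.frame(
      symbol = c(g$symbol[g$role == "TSG"], tsg_extra),
      role = "TSG", stringsAsFactors = FALSE)
  )
}

#' Write a synthetic dataset to disk in Cell Ranger v2 layout
#'
#' One directory per time point with `matrix.mtx` (Matrix Market integer
#' coordinate, genes x barcodes), `barcodes.tsv` and `genes.tsv`
#' (id TAB symbol); plus `oncogenes.tsv` / `tsgs.tsv` (symbol TAB role),
#' `ground_truth.json` and a `manifest.json` of summary counts.
#'
#' @param ds a `synthetic_dataset`.
#' @param out_dir output directory (created if missing).
#' @return `out_dir`, invisibly.
#' @export
write_dataset <- function(ds, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  for (tp in names(ds$matrices)) {
    d <- file.path(out_dir, tp)
    dir.create(d, showWarnings = FALSE)
    raw <- ds$matrices[[tp]]
    write_mtx_integer(Matrix::t(raw$counts), file.path(d, "matrix.mtx"))
    writeLines(raw$barcodes, file.path(d, "barcodes.tsv"))
    utils::write.table(raw$genes, file.path(d, "genes.tsv"), sep = "\t",
                       quote = FALSE, row.names = FALSE, col.names = FALSE)
  }
  utils::write.table(ds$catalog$oncogenes, file.path(out_dir, "oncogenes.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  utils::write.table(ds$catalog$tsgs, file.path(out_dir, "tsgs.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     col.names = FALSE)
  jsonlite::write_json(ds$truth, file.path(out_dir, "ground_truth.json"),
                       dataframe = "rows", na = "null")
  manifest <- list(
    n_time_points = length(ds$matrices),
    cells_per_timepoint = as.list(stats::setNames(
      vapply(split(ds$truth$is_cell, ds$truth$time_point), sum, 1L),
      unique(ds$truth$time_point))),
    n_oncogenes = nrow(ds$catalog$oncogenes),
    n_tsgs = nrow(ds$catalog$tsgs),
    n_genes = nrow(ds$panel$genes),
    expressed_union = sort(union(
      ds$panel$genes$symbol[ds$panel$genes$role %in% c("oncogene", "TSG")],
      unique(c(ds$catalog$oncogenes$symbol, ds$catalog$tsgs$symbol))))
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  invisible(out_dir)
}

# Matrix Market integer coordinate writer (genes x barcodes). Matrix's
# writeMM() emits "real general" headers; the Cell Ranger v2 dialect this
# package reads and writes declares "integer general", hence a local writer.
write_mtx_integer <- function(m, path) {
  tm <- methods::as(methods::as(m, "TsparseMatrix"), "generalMatrix")
  o <- order(tm@j, tm@i)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general", "%"), con)
  writeLines(sprintf("%d %d %d", nrow(tm), ncol(tm), length(tm@x)), con)
  if (length(tm@x))
    writeLines(sprintf("%d %d %d", tm@i[o] + 1L, tm@j[o] + 1L,
                       as.integer(tm@x[o])), con)
  invisible(path)
}
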