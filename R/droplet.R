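#' Raw droplet matrix constructor
#'
#' Container for the unfiltered barcode-by-gene UMI counts of one collection
#' time point, before cell calling.
#'
#' @param counts sparse nonnegative integer matrix, barcodes x genes.
#' @param barcodes character vector of droplet barcodes (rows).
#' @param genes data.frame with columns `id`, `symbol` (columns of `counts`).
#' @param time_point label of the collection time point.
#' @return object of class `raw_droplet_matrix`.
#' @export
raw_droplet_matrix <- function(counts, barcodes, genes, time_point) {
  counts <- methods::as(counts, "CsparseMatrix")
  if (nrow(counts) != length(barcodes))
    stopf("counts has %d rows but %d barcodes", nrow(counts), length(barcodes))
  if (ncol(counts) != nrow(genes))
    stopf("counts has %d columns but %d genes", ncol(counts), nrow(genes))
  if (anyDuplicated(barcodes))
    stopf("barcodes must be unique within a time point")
  if (any(counts@x < 0) || any(counts@x != floor(counts@x)))
    stopf("counts must be nonnegative integers")
  dimnames(counts) <- list(barcodes, genes$symbol)
  structure(list(counts = counts, barcodes = barcodes, genes = genes,
                 time_point = time_point),
            class = "raw_droplet_matrix")
}

#' Read a Cell Ranger v2 MTX triple
#'
#' Reads `matrix.mtx` (genes x barcodes), `barcodes.tsv` and `genes.tsv`
#' from a directory and returns the transposed barcode-by-gene matrix.
#'
#' @param dir directory containing the three files.
#' @param time_point label to attach; defaults to the directory name.
#' @return a [raw_droplet_matrix()].
#' @export
read_droplet_mtx <- function(dir, time_point = basename(dir)) {
  m <- Matrix::readMM(file.path(dir, "matrix.mtx"))
  barcodes <- readLines(file.path(dir, "barcodes.tsv"))
  genes <- utils::read.delim(file.path(dir, "genes.tsv"), header = FALSE,
                             col.names = c("id", "symbol"),
                             stringsAsFactors = FALSE)
  raw_droplet_matrix(Matrix::t(m), barcodes, genes, time_point)
}

#' Cell calling by the top-N percentile rule
#'
#' Estimates the maximum total UMI `m` as the `percentile`-th percentile of
#' the `expected_cells_N` largest barcode totals, and calls every barcode
#' whose total UMI strictly exceeds `m / divisor` as a cell. The percentile
#' is nearest-rank on the sorted top-N totals, so integer inputs give exact
#' integer thresholds; ties at exactly the threshold are not called.
#'
#' @param raw a [raw_droplet_matrix()].
#' @param expected_cells_N expected number of recovered cells (clamped to
#'   the number of barcodes, with a warning).
#' @param percentile percentile in (0, 100] (default 99).
#' @param divisor threshold divisor (default 10).
#' @return list of class `cell_calling_result`: `m`, `threshold`,
#'   `called_barcodes`, `totals`.
#' @export
call_cells <- function(raw, expected_cells_N, percentile = 99, divisor = 10) {
  stopifnot(percentile > 0, percentile <= 100, divisor > 0)
  if (expected_cells_N < 1) stopf("expected_cells_N must be >= 1")
  totals <- Matrix::rowSums(raw$counts)
  if (all(totals == 0)) stopf("no candidate cells: all barcode totals are zero")
  n_bc <- length(totals)
  if (expected_cells_N > n_bc) {
    warning(sprintf("expected_cells_N (%d) exceeds available barcodes (%d); clamping",
                    expected_cells_N, n_bc))
    expected_cells_N <- n_bc
  }
  top <- sort(totals, decreasing = TRUE)[seq_len(expected_cells_N)]
  asc <- rev(top)
  m <- unname(asc[ceiling(percentile / 100 * expected_cells_N)])
  threshold <- m / divisor
  called <- raw$barcodes[totals > threshold]
  structure(list(m = m, threshold = threshold, called_barcodes = called,
                 totals = stats::setNames(totals, raw$barcodes)),
            class = "cell_calling_result")
}

#' Pool called cells across time points into one cell matrix
#'
#' Subsets each raw matrix to its called barcodes (cell calling per time
#' point) and row-binds them over the shared gene panel.
#'
#' @param raws list of [raw_droplet_matrix()], one per time point.
#' @param expected_cells_N integer vector (recycled) of expected cells per
#'   time point, passed to [call_cells()].
#' @param percentile,divisor passed to [call_cells()].
#' @return object of class `cell_matrix`: `counts` (cells x genes, raw),
#'   `normalized` (NULL until [normalize_to_median()]), `genes`,
#'   `cell_table` (`barcode`, `time_point`, `cell_line`, `stage`), and the
#'   per-time-point `calling` results.
#' @export
pool_called_cells <- function(raws, expected_cells_N,
                              percentile = 99, divisor = 10) {
  expected_cells_N <- rep_len(expected_cells_N, length(raws))
  sym <- raws[[1]]$genes$symbol
  for (r in raws)
    if (!identical(r$genes$symbol, sym))
      stopf("all time points must share one gene panel")
  calling <- vector("list", length(raws))
  parts <- vector("list", length(raws))
  tabs <- vector("list", length(raws))
  for (i in seq_along(raws)) {
    res <- call_cells(raws[[i]], expected_cells_N[i], percentile, divisor)
    keep <- raws[[i]]$barcodes %in% res$called_barcodes
    parts[[i]] <- raws[[i]]$counts[keep, , drop = FALSE]
    tabs[[i]] <- data.frame(barcode = raws[[i]]$barcodes[keep],
                            time_point = raws[[i]]$time_point,
                            cell_line = NA_character_, stage = NA_character_,
                            stringsAsFactors = FALSE)
    calling[[i]] <- res
  }
  names(calling) <- vapply(raws, `[[`, "", "time_point")
  cell_matrix(do.call(rbind, parts), raws[[1]]$genes, do.call(rbind, tabs),
              calling = calling)
}

#' Cell matrix constructor
#' @param counts sparse raw counts, cells x genes.
#' @param genes gene annotation data.frame (`id`, `symbol`).
#' @param cell_table per-cell annotation data.frame.
#' @param normalized optional normalized matrix.
#' @param calling optional per-time-point cell-calling results.
#' @return object of class `cell_matrix`.
#' @export
cell_matrix <- function(counts, genes, cell_table, normalized = NULL,
                        calling = NULL) {
  counts <- methods::as(counts, "CsparseMatrix")
  stopifnot(nrow(counts) == nrow(cell_table), ncol(counts) == nrow(genes))
  structure(list(counts = counts, normalized = normalized, genes = genes,
                 cell_table = cell_table, calling = calling),
            class = "cell_matrix")
}

#' Assign cells to the two source lines by the Y-chromosome marker
#'
#' A cell with at least one raw UMI of the sex marker is registered as cell
#' line 1; a cell without its expression as cell line 2. Raw counts are used
#' because normalization rescales but never creates counts.
#'
#' @param cells a `cell_matrix`.
#' @param sex_marker_symbol marker gene symbol (default `"RPS4Y1"`).
#' @return `cells` with `cell_table$cell_line` filled in.
#' @export
assign_cell_line <- function(cells, sex_marker_symbol = "RPS4Y1") {
  j <- match(sex_marker_symbol, cells$genes$symbol)
  if (is.na(j))
    stopf("sex marker symbol '%s' not present in the gene panel",
          sex_marker_symbol)
  pos <- as.vector(cells$counts[, j] >= 1)
  cells$cell_table$cell_line <- ifelse(pos, "line1", "line2")
  cells
}

#' Median normalization of cell totals
#'
#' Rescales every cell by (median total UMI) / (cell total UMI) so all cells
#' share the median library size. Idempotent; the zero pattern is preserved.
#'
#' @param cells a `cell_matrix`.
#' @return `cells` with `normalized` set.
#' @export
normalize_to_median <- function(cells) {
  totals <- Matrix::rowSums(cells$counts)
  if (any(totals == 0))
    stopf("cells with zero total UMI cannot be normalized: %s",
          paste(utils::head(cells$cell_table$barcode[totals == 0], 5),
                collapse = ", "))
  med <- stats::median(totals)
  cells$normalized <- Matrix::Diagonal(x = med / totals) %*% cells$counts
  dimnames(cells$normalized) <- dimnames(cells$counts)
  cells
}

#' Quality-control summary of a cell matrix
#'
#' @param cells a `cell_matrix`.
#' @return list: `mean_genes_per_cell` (genes with >= 1 raw UMI),
#'   `mean_umi_per_cell`, `cells_per_timepoint`, `total_cells`.
#' @export
qc_summary <- function(cells) {
  if (nrow(cells$counts) < 1) stopf("qc_summary needs at least one cell")
  d <- cells$counts
  d@x <- rep(1, length(d@x))
  list(
    mean_genes_per_cell = mean(Matrix::rowSums(d)),
    mean_umi_per_cell = mean(Matrix::rowSums(cells$counts)),
    cells_per_timepoint = table(cells$cell_table$time_point),
    total_cells = nrow(cells$counts)
  )
}
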