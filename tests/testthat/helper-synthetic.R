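# Shared fixtures, generated in code and cached for the session.

.fixture_env <- new.env(parent = emptyenv())

cache <- function(name, expr) {
  if (!exists(name, envir = .fixture_env))
    assign(name, force(expr), envir = .fixture_env)
  get(name, envir = .fixture_env)
}

# One-tenth-scale study: same mixture and planted structure, ~3.2k cells.
scaled_config <- function(seed = 7L, ambient = 3000L) {
  synthetic_config(seed = seed,
                   cells_per_timepoint = c(1128L, 647L, 865L, 597L),
                   ambient_per_timepoint = ambient)
}

scaled_run <- function() {
  cache("scaled_run",
        run_pipeline(list(synthetic = scaled_config(),
                          staging = list(km_seed = 11L))))
}

# Full-scale study at the default sizes; used by the acceptance suite.
full_run <- function() {
  cache("full_run",
        run_pipeline(list(synthetic = synthetic_config(seed = 42L),
                          staging = list(km_seed = 43L))))
}

# Tiny hand-made cell_matrix from a dense counts matrix (cells x genes).
toy_cells <- function(counts, time_point = "day0", stage = NULL) {
  counts <- as.matrix(counts)
  genes <- data.frame(id = sprintf("GID%03d", seq_len(ncol(counts))),
                      symbol = colnames(counts) %||%
                        sprintf("G%03d", seq_len(ncol(counts))),
                      stringsAsFactors = FALSE)
  colnames(counts) <- genes$symbol
  ct <- data.frame(barcode = sprintf("BC%04d", seq_len(nrow(counts))),
                   time_point = rep_len(time_point, nrow(counts)),
                   cell_line = NA_character_,
                   stage = if (is.null(stage)) NA_character_ else stage,
                   stringsAsFactors = FALSE)
  cell_matrix(Matrix::Matrix(counts, sparse = TRUE), genes, ct)
}

# stage_assignment object from an explicit per-cell stage label vector
toy_assignment <- function(stage) {
  labs <- sort(unique(stage))
  structure(list(cluster = match(stage, labs), chosen_k = length(labs),
                 diagnostics = NULL, stage = stage,
                 stage_of_cluster = stats::setNames(labs, seq_along(labs))),
            class = "stage_assignment")
}

`%||%` <- function(a, b) if (is.null(a)) b else a
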