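#' Round half away from zero
#'
#' Fixed-convention rounding used for all printed percentages: ties go up
#' (0.005 -> 0.01), unlike [base::round()]'s round-half-even.
#'
#' @param x numeric vector.
#' @param digits number of decimal places.
#' @return `x` rounded half-up to `digits` decimals.
#' @export
round_half_up <- function(x, digits = 0) {
  p <- 10^digits
  # small nudge guards against e.g. 0.145*10 = 1.4499999999999997
  sign(x) * floor(abs(x) * p + 0.5 + 1e-9) / p
}

#' Roman stage labels I, II, ... for k ordered stages
#' @param k number of stages.
#' @return character vector of length `k`.
#' @export
stage_labels <- function(k) as.character(utils::as.roman(seq_len(k)))

# Ordinal rank of time-point labels ("day0" < "day2" < ...), by numeric suffix.
time_point_rank <- function(time_point) {
  lev <- unique(time_point)
  num <- suppressWarnings(as.numeric(gsub("[^0-9.]", "", lev)))
  if (anyNA(num)) num <- seq_along(lev)
  match(time_point, lev[order(num)])
}

`%||%` <- function(a, b) if (is.null(a)) b else a

stopf <- function(...) stop(sprintf(...), call. = FALSE)
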