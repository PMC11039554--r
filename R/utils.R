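#' Trapezoidal integral
#'
#' @param x abscissa (monotone increasing) or, if `y` is missing, `y` values
#'   on a unit-spaced grid.
#' @param y ordinates.
#' @return The trapezoid-rule integral as a scalar.
#' @keywords internal
trapz <- function(x, y = NULL) {
  if (is.null(y)) {
    y <- x
    x <- seq_along(y)
  }
  stopifnot(length(x) == length(y), length(x) >= 2)
  sum(diff(x) * (head(y, -1) + y[-1]) / 2)
}

## round-half-away-from-zero; base round() rounds half to even
round_half_up <- function(x) {
  floor(x + 0.5)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Log a pipeline stage to stderr with a timestamp
#' @keywords internal
log_stage <- function(fmt, ...) {
  message(sprintf("[iscn %s] %s", format(Sys.time(), "%H:%M:%S"),
                  sprintf(fmt, ...)))
}

## Deterministic surrogate-network seed for (base seed, subject, density K).
## Keeps the derived seed well below 2^31 for typical inputs.
surrogate_seed <- function(seed, subject_index, k) {
  as.integer((seed + 7919L * subject_index + as.integer(round(k))) %% .Machine$integer.max)
}

## Upper-triangle (i < j) index pairs in column-major order, the order in
## which `mat[upper.tri(mat)]` linearises a symmetric matrix.
edge_index_pairs <- function(n_regions) {
  idx <- which(upper.tri(matrix(0, n_regions, n_regions)), arr.ind = TRUE)
  data.frame(i = unname(idx[, 1]), j = unname(idx[, 2]))
}

## Names for the upper-triangle edge features of an R-region network, in the
## same column-major order as edge_index_pairs(): edge_r001_r002, ...
edge_feature_names <- function(region_ids) {
  idx <- edge_index_pairs(length(region_ids))
  sprintf("edge_r%03d_r%03d", region_ids[idx$i], region_ids[idx$j])
}
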