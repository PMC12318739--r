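#' Round to the nearest integer with ties going up
#'
#' Consensus labels and imputed ratings use a single documented rounding
#' rule: `.5` ties round toward the larger integer (`round_half_up(2.5)` is
#' `3`), unlike base [round()], which rounds half to even. Banker's rounding
#' is available through the `rounding` argument of the functions that
#' consume this helper so cohort counts can be validated under both rules.
#'
#' @param x Numeric vector.
#' @return Integer-valued numeric vector.
#' @export
#' @examples
#' round_half_up(c(2.5, 3.5, -0.5, 2.4))
round_half_up <- function(x) floor(x + 0.5)

round_by_rule <- function(x, rounding = c("half_up", "banker")) {
  rounding <- match.arg(rounding)
  if (rounding == "half_up") round_half_up(x) else round(x)
}

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Row-wise softmax
#'
#' Numerically stable softmax applied independently to each row of a matrix;
#' every output row sums to one. Used by the attention modules.
#'
#' @param m Numeric matrix.
#' @return Matrix of the same shape with non-negative rows summing to 1.
#' @keywords internal
softmax_rows <- function(m) {
  row_max <- m[cbind(seq_len(nrow(m)), max.col(m, ties.method = "first"))]
  e <- exp(m - row_max)
  e / rowSums(e)
}

# Derive a child seed from a base seed and a stream index, kept < 2^31.
derive_seed <- function(seed, stream) {
  (as.numeric(seed) * 7919 + 104729 * as.numeric(stream)) %% 2147483647
}

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_finite_matrix <- function(m) is.numeric(m) && all(is.finite(m))
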