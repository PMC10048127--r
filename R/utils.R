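#' Round half away from zero
#'
#' Decimal rounding where exact halves round up (`0.005 -> 0.01`), matching
#' how the caries summary tables print percentages. Base R's [round()] uses
#' banker's rounding and would print e.g. 2.565 as 2.56.
#'
#' @param x Numeric vector.
#' @param digits Number of decimal places.
#' @return Rounded numeric vector.
#' @export
round_half_up <- function(x, digits = 2) {
  m <- 10^digits
  sign(x) * floor(abs(x) * m + 0.5) / m
}

# stable log(sum(exp(x))) by row for a matrix
.row_logsumexp <- function(lw) {
  m <- apply(lw, 1, max)
  m + log(rowSums(exp(lw - m)))
}

.stopf <- function(...) stop(sprintf(...), call. = FALSE)

.assert_prob_range <- function(x, name) {
  if (anyNA(x) || any(x < 0) || any(x > 1)) {
    .stopf("`%s` must lie in [0, 1].", name)
  }
}

# column standardization that tolerates constant columns (scale set to 1,
# so a centered constant column is identically zero and stays unpenalized at 0)
.standardize <- function(X) {
  center <- colMeans(X)
  scale <- apply(X, 2, stats::sd)
  scale[!is.finite(scale) | scale < .Machine$double.eps] <- 1
  Xs <- sweep(sweep(X, 2, center, "-"), 2, scale, "/")
  list(X = Xs, center = center, scale = scale)
}
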