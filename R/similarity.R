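#' Cosine similarity between two channel vectors
#'
#' @param a,b Nonnegative numeric vectors of equal length.
#' @return `dot(a, b) / (|a| |b|)`, in `[0, 1]` for nonnegative input;
#'   scale-invariant.
#' @export
cosine_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  na <- sqrt(sum(a^2)); nb <- sqrt(sum(b^2))
  if (na == 0 || nb == 0) stop("cosine similarity undefined for zero vector")
  sum(a * b) / (na * nb)
}

#' Spearman rank correlation between two channel vectors
#'
#' Rank-transforms both vectors (average ranks for ties) and computes the
#' Pearson correlation of the ranks.
#'
#' @param a,b Numeric vectors of equal length.
#' @return Correlation in `[-1, 1]`.
#' @export
spearman_similarity <- function(a, b) {
  if (length(a) != length(b)) stop("vectors differ in length")
  if (stats::sd(a) == 0 || stats::sd(b) == 0)
    stop("rank correlation undefined for constant vector")
  stats::cor(a, b, method = "spearman")
}
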