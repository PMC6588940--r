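#' Median-of-ratios size factors
#'
#' For each feature with strictly positive counts in every sample, the
#' geometric mean across samples is computed; a sample's size factor is
#' the median over those features of the ratio of its count to the
#' feature's geometric mean (the median taken on the log scale, the
#' standard convention, which matters only when the reference feature
#' count is even). Features with any zero count are excluded from the
#' reference set.
#'
#' @param counts Numeric matrix, features x samples (>= 2 samples).
#' @return Named numeric vector of positive size factors.
#' @examples
#' m <- cbind(a = c(10, 20, 30), b = c(20, 40, 60))
#' size_factors(m) # c(1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(counts) {
  counts <- as.matrix(counts)
  if (ncol(counts) < 2) stop("size factors need at least 2 samples")
  pos <- rowSums(counts <= 0) == 0
  if (!any(pos))
    stop("no feature has all-positive counts; median-of-ratios is undefined")
  logc <- log(counts[pos, , drop = FALSE])
  geomean <- rowMeans(logc)
  exp(apply(logc - geomean, 2, stats::median))
}

#' Normalize a count matrix by size factors
#'
#' @param counts Numeric matrix, features x samples.
#' @param factors Size factors from [size_factors()] (recomputed when
#'   omitted).
#' @return Matrix of normalized counts `counts[i,j] / factors[j]`, with
#'   the factors attached as `attr(, "size_factors")`.
#' @export
normalize_counts <- function(counts, factors = NULL) {
  counts <- as.matrix(counts)
  if (is.null(factors)) factors <- size_factors(counts)
  if (any(factors <= 0)) stop("size factors must be positive")
  out <- sweep(counts, 2, factors, "/")
  attr(out, "size_factors") <- factors
  out
}
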