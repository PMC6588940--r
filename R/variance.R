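#' Per-sequence feature table
#'
#' Computes the sequence characteristics used to explain technical
#' variance: GC content, length, fold energy (supplied, or the
#' maximum-base-pairing proxy), the identity of the first and last two
#' bases, per-base counts, and repeat flags (`has_duplet`: any two
#' identical adjacent bases; `has_quadruplet`: any run of four identical
#' bases).
#'
#' @param sequences Character vector over A/C/G/T (U is accepted and
#'   converted), each >= 16 nt.
#' @param fold_g Optional numeric fold energies (kcal/mol), parallel to
#'   `sequences`; when omitted the proxy is used and the result carries
#'   `attr(, "fold_g_proxy") = TRUE`.
#' @return data.frame with columns `sequence`, `gc_content`, `length`,
#'   `fold_g`, `first2`, `last2`, `nA`, `nC`, `nG`, `nT`, `has_duplet`,
#'   `has_quadruplet`.
#' @examples
#' sequence_features("GGGGCCCCAAAATTTTGGGG", fold_g = -5)
#' @export
sequence_features <- function(sequences, fold_g = NULL) {
  sequences <- chartr("U", "T", toupper(sequences))
  if (any(grepl("[^ACGT]", sequences)))
    stop("sequences must be over the A/C/G/T (or U) alphabet")
  if (any(nchar(sequences) < 16)) stop("sequences must be >= 16 nt")
  proxy <- FALSE
  if (is.null(fold_g)) {
    fold_g <- as.numeric(fold_energy_proxy(sequences))
    proxy <- TRUE
  }
  if (length(fold_g) != length(sequences))
    stop("fold_g must be parallel to sequences")
  n <- nchar(sequences)
  count_base <- function(b)
    n - nchar(gsub(b, "", sequences, fixed = TRUE))
  out <- data.frame(
    sequence = sequences,
    gc_content = gc_fraction(sequences),
    length = n,
    fold_g = fold_g,
    first2 = substr(sequences, 1, 2),
    last2 = substr(sequences, n - 1, n),
    nA = count_base("A"), nC = count_base("C"),
    nG = count_base("G"), nT = count_base("T"),
    has_duplet = grepl("([ACGT])\\1", sequences),
    has_quadruplet = grepl("([ACGT])\\1{3}", sequences),
    stringsAsFactors = FALSE
  )
  attr(out, "fold_g_proxy") <- proxy
  out
}

#' Percent variance explained per factor (type-II sums of squares)
#'
#' Fits the least-squares model of `response` on all factors jointly
#' (treatment coding, first level by lexicographic order) and attributes
#' to each factor the type-II sum of squares — the residual-sum-of-squares
#' increase when that factor alone is removed from the full model — as a
#' percentage of the total sum of squares. In an orthogonal design the
#' factor percentages plus the residual percentage sum to 100 and type-II
#' shares equal sequential (type-I) shares; in non-orthogonal designs
#' shares need not sum to 100, and any negative share is floored at zero
#' with a warning.
#'
#' @param response Numeric vector (one value per observation/feature).
#' @param factors data.frame of explanatory columns (numeric or
#'   categorical), e.g. a subset of [sequence_features()] columns or a
#'   design table.
#' @return A `variance_decomposition`: list with `percent` (named, per
#'   factor), `residual_percent`, `ss` (per-factor type-II SS),
#'   `ss_total`.
#' @export
percent_variance <- function(response, factors) {
  factors <- as.data.frame(factors)
  stopifnot(length(response) == nrow(factors))
  for (j in seq_along(factors))
    if (is.character(factors[[j]]) || is.logical(factors[[j]]))
      factors[[j]] <- factor(factors[[j]])
  for (j in seq_along(factors))
    if (is.factor(factors[[j]]) && nlevels(droplevels(factors[[j]])) < 2)
      stop("factor '", names(factors)[j], "' has fewer than 2 observed levels")

  dat <- data.frame(.y = response, factors, check.names = FALSE)
  full <- stats::lm(stats::reformulate(names(factors), response = ".y"),
                    data = dat)
  p_full <- full$rank
  if (length(response) <= p_full)
    stop("need more observations than model parameters")
  X <- stats::model.matrix(full)
  if (qr(X)$rank < ncol(X)) {
    ali <- stats::alias(full)$Complete
    stop("rank-deficient design; aliased terms: ",
         paste(rownames(ali), collapse = ", "))
  }

  rss <- function(fit) sum(stats::residuals(fit)^2)
  rss_full <- rss(full)
  ss_total <- sum((response - mean(response))^2)
  ss <- vapply(names(factors), function(f) {
    others <- setdiff(names(factors), f)
    reduced <- if (length(others))
      stats::lm(stats::reformulate(others, response = ".y"), data = dat)
    else stats::lm(.y ~ 1, data = dat)
    rss(reduced) - rss_full
  }, numeric(1))

  if (any(ss < 0)) {
    warning("negative type-II components floored at 0 (non-orthogonal design)")
    ss[ss < 0] <- 0
  }
  structure(list(percent = 100 * ss / ss_total,
                 residual_percent = 100 * rss_full / ss_total,
                 ss = ss, ss_total = ss_total),
            class = "variance_decomposition")
}

#' Variance-weighted view of per-method decompositions
#'
#' Rescales each method's percent-variance shares by that method's overall
#' response variance relative to the noisiest method:
#' `weighted(method, factor) = percent(method, factor) * var(method) /
#' max(var)`. Methods with equal variance are unchanged; a method with
#' half the maximal variance has its shares halved, so a factor's weighted
#' share ranks methods by how much absolute variance the factor drives.
#'
#' @param decompositions Named list of `variance_decomposition` objects,
#'   one per method.
#' @param method_variances Named numeric of overall per-method variances.
#' @return Matrix (factor x method) of weighted percent shares.
#' @export
weighted_percent_variance <- function(decompositions, method_variances) {
  stopifnot(length(decompositions) >= 1,
            setequal(names(decompositions), names(method_variances)))
  w <- method_variances / max(method_variances)
  cols <- lapply(names(decompositions), function(m)
    decompositions[[m]]$percent * w[[m]])
  out <- do.call(cbind, cols)
  colnames(out) <- names(decompositions)
  out
}
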