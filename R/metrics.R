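#' Accuracy error of an equimolar quantification
#'
#' For an equimolar pool every sequence should be quantified at the common
#' mean, so the per-sequence error is the log2-transformed absolute
#' deviation from the mean of all sequences:
#' `log2(|x_i - mean(x)| + 1)`. The +1 pseudocount maps a zero deviation
#' to zero error and keeps the transform defined (a deliberate guard the
#' plain log2 of an absolute difference lacks).
#'
#' @param normalized Numeric vector of normalized counts for one sample or
#'   method (>= 2 features), or a matrix (features x samples) to get one
#'   error column per sample.
#' @return Per-feature errors (vector or matrix matching the input shape).
#' @examples
#' accuracy_error(c(120, 80, 100, 100)) # log2(21), log2(21), 0, 0
#' @export
accuracy_error <- function(normalized) {
  if (is.matrix(normalized)) {
    if (nrow(normalized) < 2) stop("accuracy error needs >= 2 features")
    return(apply(normalized, 2, accuracy_error))
  }
  if (length(normalized) < 2) stop("accuracy error needs >= 2 features")
  log2(abs(normalized - mean(normalized)) + 1)
}

#' Detected feature sets at a normalized-count threshold
#'
#' A feature is detected in a replicate when its normalized count is
#' strictly greater than the threshold (10 for miRNAs, 100 for isomiRs);
#' the consensus set is the intersection across all replicates of the
#' group.
#'
#' @param normalized Matrix of normalized counts (features x replicates).
#' @param threshold Strict detection threshold (> threshold).
#' @return A `detection_set`: list with `per_replicate` (list of feature
#'   id vectors), `consensus`, and `threshold`.
#' @export
detect <- function(normalized, threshold = 10) {
  stopifnot(threshold > 0)
  normalized <- as.matrix(normalized)
  ids <- rownames(normalized)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(normalized)))
  per_rep <- lapply(seq_len(ncol(normalized)),
                    function(j) ids[normalized[, j] > threshold])
  names(per_rep) <- colnames(normalized)
  structure(list(per_replicate = per_rep,
                 consensus = Reduce(intersect, per_rep),
                 threshold = threshold),
            class = "detection_set")
}

#' Detection inconsistency percentage per replicate
#'
#' The fraction of a replicate's detected features that are absent from
#' the replicate-consensus set: `(U_X - U_123) / U_X * 100`, where `U_X`
#' is the replicate's detected count and `U_123` the count detected in
#' all replicates. Zero when a replicate equals the consensus; `NA` when
#' the replicate detected nothing.
#'
#' @param detection A `detection_set` from [detect()].
#' @return Numeric vector of percentages, one per replicate.
#' @examples
#' d <- structure(list(per_replicate = list(c("a","b","c"), c("a","b"), c("a","b")),
#'                     consensus = c("a","b"), threshold = 10),
#'                class = "detection_set")
#' detection_inconsistency(d) # 33.33, 0, 0
#' @export
detection_inconsistency <- function(detection) {
  u123 <- length(detection$consensus)
  vapply(detection$per_replicate, function(s) {
    ux <- length(s)
    if (ux == 0) return(NA_real_)
    (ux - u123) / ux * 100
  }, numeric(1))
}

#' False-isomiR summaries for an equimolar synthetic run
#'
#' In an equimolar synthetic pool no isomiRs exist by design, so every
#' isomiR detected above the threshold (strictly more than 100 normalized
#' reads) is a false positive. Summarized along the three comparison
#' axes: total unique detected isomiR sequences, the number per parent
#' sequence, and the expression of the individual false isomiRs.
#'
#' @param isomir_normalized Normalized isomiR count matrix with rownames
#'   `parent|sequence` (features x samples); a vector is treated as one
#'   sample.
#' @param threshold Strict detection threshold (default 100).
#' @return List per sample with `total_unique`, `per_parent` (named
#'   integer, zero-filled over all parents seen in the table), and
#'   `expression` (named numeric for detected isomiRs).
#' @export
false_isomirs <- function(isomir_normalized, threshold = 100) {
  m <- as.matrix(isomir_normalized)
  if (is.null(rownames(m)) && nrow(m) > 0)
    stop("isomiR matrix must have 'parent|sequence' rownames")
  parents_all <- unique(sub("\\|.*$", "", rownames(m)))
  one <- function(x) {
    det <- which(x > threshold)
    parents <- sub("\\|.*$", "", rownames(m)[det])
    per_parent <- stats::setNames(integer(length(parents_all)), parents_all)
    if (length(det)) {
      tab <- table(parents)
      per_parent[names(tab)] <- as.integer(tab)
    }
    list(total_unique = length(det), per_parent = per_parent,
         expression = stats::setNames(x[det], rownames(m)[det]))
  }
  out <- lapply(seq_len(ncol(m)), function(j) one(m[, j]))
  names(out) <- colnames(m)
  out
}

#' MA statistics between two methods
#'
#' Per-feature log-ratio (M) and average log expression (A) between the
#' mean normalized quantifications of two methods, after restricting to
#' features with normalized counts strictly greater than one in every
#' sample of both methods:
#' `M_i = log2(meanA_i) - log2(meanB_i)`,
#' `A_i = (log2(meanA_i) + log2(meanB_i)) / 2`.
#'
#' @param normA,normB Normalized count matrices (features x samples) for
#'   the two methods, sharing rownames.
#' @param expression_floor Strict per-sample filter (default 1).
#' @return data.frame with `feature`, `A`, `M` for the retained features.
#' @export
ma_statistics <- function(normA, normB, expression_floor = 1) {
  normA <- as.matrix(normA); normB <- as.matrix(normB)
  common <- intersect(rownames(normA), rownames(normB))
  normA <- normA[common, , drop = FALSE]
  normB <- normB[common, , drop = FALSE]
  keep <- rowSums(normA <= expression_floor) == 0 &
    rowSums(normB <= expression_floor) == 0
  la <- log2(rowMeans(normA[keep, , drop = FALSE]))
  lb <- log2(rowMeans(normB[keep, , drop = FALSE]))
  data.frame(feature = common[keep], A = (la + lb) / 2, M = la - lb,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Overlap of the top-n most abundant features across methods
#'
#' Ranks features per method by mean normalized count (descending; ties at
#' the boundary broken lexicographically by feature id) and reports the
#' fraction of the top n shared by all methods, plus all pairwise
#' fractions.
#'
#' @param method_means Named list of per-feature mean normalized counts
#'   (named numeric vectors), one per method.
#' @param n Size of the abundance ranking (default 20).
#' @return List with `global` (|intersection| / n), `pairwise` (named
#'   numeric), and `top` (the per-method top-n id lists).
#' @export
topn_overlap <- function(method_means, n = 20) {
  top <- lapply(method_means, function(x) {
    if (length(x) < n) stop("n exceeds the feature count")
    ids <- names(x)
    ord <- order(-x, ids)
    ids[ord][seq_len(n)]
  })
  global <- length(Reduce(intersect, top)) / n
  pairs <- utils::combn(names(top), 2, simplify = FALSE)
  pairwise <- vapply(pairs, function(p)
    length(intersect(top[[p[1]]], top[[p[2]]])) / n, numeric(1))
  names(pairwise) <- vapply(pairs, paste, character(1), collapse = ":")
  list(global = global, pairwise = pairwise, top = top)
}

#' Batch consistency error
#'
#' Per-feature log2 absolute difference between the mean of the
#' first-batch triplicates and the second-batch quantification, after
#' filtering for features with normalized counts strictly greater than
#' `filter_threshold` in all samples:
#' `log2(|mean(batch1_i) - batch2_i| + 1)` (+1 pseudocount, as in
#' [accuracy_error()]).
#'
#' @param batch1 Normalized matrix (features x replicates) of batch 1.
#' @param batch2 Named numeric vector (or 1-column matrix) of batch 2.
#' @param filter_threshold Strict filter (default 10).
#' @return Named numeric vector of per-feature batch errors.
#' @export
batch_error <- function(batch1, batch2, filter_threshold = 10) {
  batch1 <- as.matrix(batch1)
  batch2 <- drop(as.matrix(batch2))
  common <- intersect(rownames(batch1), names(batch2))
  batch1 <- batch1[common, , drop = FALSE]
  batch2 <- batch2[common]
  keep <- rowSums(batch1 <= filter_threshold) == 0 &
    batch2 > filter_threshold
  log2(abs(rowMeans(batch1[keep, , drop = FALSE]) - batch2[keep]) + 1)
}

#' Triplicate consistency error
#'
#' Each replicate's error for a feature is the log2 absolute deviation
#' from the mean of its replicates (`log2(|x - mean| + 1)`); the
#' per-feature value is the mean over replicates.
#'
#' @param replicates Normalized matrix (features x replicates, k >= 2).
#' @return Named numeric vector of per-feature mean errors.
#' @examples
#' triplicate_error(matrix(c(90, 100, 110), 1,
#'                  dimnames = list("x", NULL))) # mean(log2(11), 0, log2(11))
#' @export
triplicate_error <- function(replicates) {
  replicates <- as.matrix(replicates)
  if (ncol(replicates) < 2) stop("triplicate error needs >= 2 replicates")
  m <- rowMeans(replicates)
  rowMeans(log2(abs(replicates - m) + 1))
}

#' Estimate pre-PCR starting molecules from a read count
#'
#' Inverts the expected amplification factor: after `c` cycles at
#' per-cycle duplication probability `e`, one molecule yields
#' `(1+e)^c` copies in expectation, so `N0 = reads / (1+e)^c`. The
#' default efficiency 0.625 is deliberately conservative (real miRNA PCR
#' efficiencies usually run 0.75-0.95), making the estimate an upper
#' bound on the starting count. Estimates approaching the UMI label
#' space are flagged as saturating, since distinct-UMI counting then
#' undercounts molecules.
#'
#' @param reads Observed read count(s).
#' @param efficiency Per-cycle duplication probability in (0, 1].
#' @param cycles Number of PCR cycles.
#' @param umi_space UMI label count (default `umi_space_size(4)` = 65,536).
#' @param saturation_ratio Flag threshold on `N0 / umi_space`.
#' @return data.frame with `reads`, `n0`, `saturating`.
#' @examples
#' estimate_starting_molecules(1e6, 0.625, 18)$n0 # ~160.4
#' @export
estimate_starting_molecules <- function(reads, efficiency = 0.625,
                                        cycles = 18,
                                        umi_space = umi_space_size(4),
                                        saturation_ratio = 0.2) {
  stopifnot(efficiency > 0, efficiency <= 1, cycles >= 0)
  n0 <- reads / (1 + efficiency)^cycles
  data.frame(reads = reads, n0 = n0,
             saturating = n0 / umi_space > saturation_ratio)
}
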