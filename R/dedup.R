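#' Group assigned reads by reference, collecting UMI counts
#'
#' Groups reads by their assigned reference (liberal grouping: canonical
#' reads and isomiRs of the same reference fall into one group, so an
#' isomiR paired with the same UMI as its reference is treated as a
#' duplicate). UMIs are taken from the underscore suffix of the read
#' identifier.
#'
#' @param read_ids Character vector of UMI-suffixed read identifiers
#'   (`"<id>_<UMI>"`).
#' @param parent_ids Parallel vector of assigned reference ids (`NA` rows
#'   are dropped as unassigned).
#' @return Named list (one element per reference) of named integer
#'   UMI-count vectors (`umi_groups`).
#' @export
group_reads_by_reference <- function(read_ids, parent_ids) {
  stopifnot(length(read_ids) == length(parent_ids))
  keep <- !is.na(parent_ids)
  read_ids <- read_ids[keep]; parent_ids <- parent_ids[keep]
  if (any(!grepl("_[ACGTN]+$", read_ids)))
    stop("read identifiers must carry a UMI as an underscore suffix (\"id_UMI\")")
  umi <- sub(".*_", "", read_ids)
  groups <- lapply(split(umi, parent_ids), function(u) {
    tab <- table(u)
    stats::setNames(as.integer(tab), names(tab))
  })
  structure(groups, class = "umi_groups")
}

#' Directional UMI clustering
#'
#' The directional error-correcting method: a directed edge runs from UMI
#' `a` to UMI `b` when they differ at exactly one position and
#' `count(a) >= 2 * count(b) - 1`; clusters are grown by breadth-first
#' search from unvisited seeds taken in order of decreasing count (ties
#' broken lexicographically), following directed edges transitively. The
#' cluster count estimates the number of distinct starting molecules while
#' absorbing UMIs that look like sequencing errors of a more abundant UMI.
#'
#' @param umi_counts Named integer vector (names = UMIs, equal length;
#'   counts >= 1).
#' @param count_ratio Threshold multiplier of the directional rule
#'   (default 2, giving `count(a) >= 2*count(b) - 1`).
#' @param max_hamming Adjacency distance (default 1).
#' @return List with `n_clusters`, `representatives` (seed UMI per
#'   cluster), and `membership` (named integer cluster index per UMI).
#' @examples
#' directional_cluster(c(AAAA = 10, AAAT = 1))$n_clusters # 1
#' directional_cluster(c(AAAA = 3, AAAT = 3))$n_clusters  # 2
#' @export
directional_cluster <- function(umi_counts, count_ratio = 2,
                                max_hamming = 1L) {
  stopifnot(length(umi_counts) >= 1, all(umi_counts >= 1))
  umis <- names(umi_counts)
  if (is.null(umis) || any(!nzchar(umis))) stop("umi_counts must be named")
  if (length(unique(nchar(umis))) != 1L)
    stop("all UMIs must have equal length")

  n <- length(umis)
  ord <- order(-umi_counts, umis)
  if (n == 1L)
    return(list(n_clusters = 1L, representatives = umis,
                membership = stats::setNames(1L, umis)))

  # pairwise Hamming distances over a base matrix
  chars <- matrix(unlist(strsplit(umis, "")), nrow = n, byrow = TRUE)
  adj <- vector("list", n)
  for (i in seq_len(n)) {
    d <- rowSums(chars != matrix(chars[i, ], nrow = n, ncol = ncol(chars),
                                 byrow = TRUE))
    near <- which(d > 0 & d <= max_hamming)
    # directed: i -> j allowed when count(i) >= ratio * count(j) - 1
    adj[[i]] <- near[umi_counts[i] >= count_ratio * umi_counts[near] - 1]
  }

  membership <- stats::setNames(rep(NA_integer_, n), umis)
  reps <- character(0)
  cl <- 0L
  for (s in ord) {
    if (!is.na(membership[s])) next
    cl <- cl + 1L
    reps <- c(reps, umis[s])
    queue <- s
    membership[s] <- cl
    while (length(queue)) {
      v <- queue[1]; queue <- queue[-1]
      nxt <- adj[[v]][is.na(membership[adj[[v]]])]
      membership[nxt] <- cl
      queue <- c(queue, nxt)
    }
  }
  list(n_clusters = cl, representatives = reps, membership = membership)
}

#' Deduplicated counts per reference
#'
#' The deduplicated count of a reference is its number of directional UMI
#' clusters — an estimate of pre-amplification molecules. Always at most
#' the raw read count.
#'
#' @param groups `umi_groups` from [group_reads_by_reference()].
#' @return Named integer vector of deduplicated counts.
#' @export
dedup_counts <- function(groups) {
  vapply(groups, function(g) directional_cluster(g)$n_clusters, integer(1))
}

#' Random subsample of a read set
#'
#' Keeps each read independently with probability `fraction` — the
#' "five percent" control used to separate the effect of UMI collapsing
#' from the effect of simply having fewer reads.
#'
#' @param reads A `read_set`.
#' @param fraction Keep probability in (0, 1].
#' @param seed Integer seed or `NULL`.
#' @return A `read_set` subset; deterministic per seed.
#' @export
subsample_reads <- function(reads, fraction = 0.05, seed = NULL) {
  stopifnot(fraction > 0, fraction <= 1)
  maybe_set_seed(seed)
  keep <- stats::runif(nrow(reads)) < fraction
  out <- reads[keep, , drop = FALSE]
  attr(out, "umi_dialect") <- attr(reads, "umi_dialect")
  class(out) <- c("read_set", "data.frame")
  out
}
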