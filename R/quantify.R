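#' isomiR assignment policy
#'
#' Explicit bounds for assigning an insert to a reference as a canonical
#' read or isomiR: maximum 5'/3' end offsets, internal mismatches within
#' the aligned core, and 3' non-templated additions. The assignment cost
#' of a candidate alignment is the sum `|5' offset| + 3' offset +
#' internal mismatches + non-templated additions`.
#'
#' @param max_5p_offset,max_3p_offset,max_internal_mismatch,max_nt_additions3
#'   Nonnegative integer bounds.
#' @return An `assignment_policy` list.
#' @export
assignment_policy <- function(max_5p_offset = 4L, max_3p_offset = 4L,
                              max_internal_mismatch = 2L,
                              max_nt_additions3 = 3L) {
  vals <- c(max_5p_offset, max_3p_offset, max_internal_mismatch,
            max_nt_additions3)
  if (any(vals < 0)) stop("assignment policy bounds must be nonnegative")
  structure(list(max_5p_offset = as.integer(max_5p_offset),
                 max_3p_offset = as.integer(max_3p_offset),
                 max_internal_mismatch = as.integer(max_internal_mismatch),
                 max_nt_additions3 = as.integer(max_nt_additions3)),
            class = "assignment_policy")
}

# minimal assignment cost of insert against one reference, or Inf if no
# alignment satisfies the policy bounds
score_against_reference <- function(insert, ref, policy) {
  ni <- nchar(insert); nr <- nchar(ref)
  ic <- utf8ToInt(insert); rc <- utf8ToInt(ref)
  best <- Inf
  for (o5 in -policy$max_5p_offset:policy$max_5p_offset) {
    # o5 > 0: insert is 5'-truncated by o5; o5 < 0: insert carries |o5|
    # extra 5' bases absent from the reference
    i_start <- if (o5 < 0) -o5 + 1L else 1L
    r_start <- if (o5 > 0) o5 + 1L else 1L
    li <- ni - i_start + 1L
    lr <- nr - r_start + 1L
    if (li < 1L || lr < 1L) next
    ov <- min(li, lr)
    mism <- sum(ic[i_start:(i_start + ov - 1L)] != rc[r_start:(r_start + ov - 1L)])
    if (mism > policy$max_internal_mismatch) next
    add <- max(0L, li - lr)   # insert overhang at 3' = non-templated additions
    o3 <- max(0L, lr - li)    # reference overhang at 3' = 3' trimming offset
    if (add > policy$max_nt_additions3 || o3 > policy$max_3p_offset) next
    cost <- abs(o5) + o3 + mism + add
    if (cost < best) best <- cost
  }
  best
}

#' Assign a single insert to a reference pool
#'
#' Exact matches to a canonical sequence are canonical; otherwise the
#' reference minimizing the assignment cost within the policy bounds is
#' chosen (isomiR), with ties broken by smallest cost then
#' lexicographically smallest reference id; an insert with no reference
#' within bounds is unassigned.
#'
#' @param insert Insert sequence (>= 16 nt for meaningful assignment).
#' @param pool A `reference_pool`.
#' @param policy An `assignment_policy`.
#' @return List with `parent_id` (or `NA`), `is_canonical`, `cost`.
#' @export
assign_read <- function(insert, pool, policy = assignment_policy()) {
  hit <- match(insert, pool$sequence)
  if (!is.na(hit))
    return(list(parent_id = pool$id[hit], is_canonical = TRUE, cost = 0L))
  costs <- vapply(pool$sequence, score_against_reference,
                  numeric(1), insert = insert, policy = policy,
                  USE.NAMES = FALSE)
  if (all(!is.finite(costs)))
    return(list(parent_id = NA_character_, is_canonical = FALSE, cost = NA_real_))
  best <- min(costs)
  cand <- sort(pool$id[costs == best])
  list(parent_id = cand[1], is_canonical = FALSE, cost = best)
}

#' Assign many inserts to a reference pool
#'
#' Vectorized driver for [assign_read()]: unique inserts are scored once
#' (exact canonical matches short-circuit the policy search) and results
#' are mapped back to all reads.
#'
#' @param inserts Character vector of insert sequences.
#' @param pool A `reference_pool`.
#' @param policy An `assignment_policy`.
#' @return data.frame with `insert`, `parent_id`, `is_canonical`, `cost`
#'   (one row per input read; unassigned rows have `NA` parent).
#' @export
assign_reads <- function(inserts, pool, policy = assignment_policy()) {
  validate_reference_pool(pool)
  u <- unique(inserts)
  exact <- match(u, pool$sequence)
  parent <- pool$id[exact]
  canonical <- !is.na(exact)
  cost <- ifelse(canonical, 0, NA_real_)
  todo <- which(!canonical)
  for (i in todo) {
    a <- assign_read(u[i], pool, policy)
    parent[i] <- a$parent_id
    cost[i] <- a$cost
  }
  j <- match(inserts, u)
  data.frame(insert = inserts, parent_id = parent[j],
             is_canonical = canonical[j], cost = cost[j],
             stringsAsFactors = FALSE)
}

#' Build canonical and isomiR count matrices across samples
#'
#' Tabulates per-sample assignments into a canonical count matrix
#' (reference x sample) and an isomiR count matrix keyed by
#' (parent id, full insert sequence) — the sequence-level isomiR identity.
#' Unassigned reads are tallied per sample.
#'
#' @param assignments Named list (one element per sample) of data.frames
#'   from [assign_reads()].
#' @param pool A `reference_pool` (fixes the canonical row set).
#' @param metadata Optional data.frame with one row per sample
#'   (e.g. method, input_ng, batch, replicate).
#' @return A `count_matrix`: list with `canonical` (integer matrix),
#'   `isomir` (integer matrix with rownames `parent|sequence`),
#'   `unassigned` (named integer), `metadata`.
#' @export
build_count_matrix <- function(assignments, pool, metadata = NULL) {
  validate_reference_pool(pool)
  samples <- names(assignments)
  if (is.null(samples) || any(!nzchar(samples)))
    stop("assignments must be a named list of per-sample tables")
  if (anyDuplicated(samples)) stop("duplicate sample names")

  canonical <- matrix(0L, nrow = nrow(pool), ncol = length(samples),
                      dimnames = list(pool$id, samples))
  iso_keys <- character(0)
  iso_cols <- list()
  unassigned <- integer(length(samples)); names(unassigned) <- samples

  for (s in samples) {
    a <- assignments[[s]]
    unassigned[s] <- sum(is.na(a$parent_id))
    can <- a[a$is_canonical %in% TRUE, , drop = FALSE]
    if (nrow(can)) {
      tab <- table(can$parent_id)
      canonical[names(tab), s] <- as.integer(tab)
    }
    iso <- a[!is.na(a$parent_id) & !a$is_canonical, , drop = FALSE]
    if (nrow(iso)) {
      key <- paste(iso$parent_id, iso$insert, sep = "|")
      tab <- table(key)
      iso_cols[[s]] <- tab
      iso_keys <- union(iso_keys, names(tab))
    }
  }
  isomir <- matrix(0L, nrow = length(iso_keys), ncol = length(samples),
                   dimnames = list(iso_keys, samples))
  for (s in names(iso_cols))
    isomir[names(iso_cols[[s]]), s] <- as.integer(iso_cols[[s]])

  out <- list(canonical = canonical, isomir = isomir,
              unassigned = unassigned, metadata = metadata)
  class(out) <- "count_matrix"
  out
}

#' Classify reads among labeled small-RNA classes
#'
#' Seed-style exact matching: a read is assigned to a class entry if its
#' first `min(seed_length, read length)` bases occur verbatim (forward
#' strand) within the entry sequence. At reference build time, piRNA
#' entries whose sequence exactly equals a miRNA entry are removed from
#' the piRNA portion, so such reads count as miRNA. Reads matching no
#' entry are `"Undetermined"`. When a read matches entries of several
#' classes, the class listed first in `reference` wins.
#'
#' @param sequences Character vector of read/insert sequences.
#' @param reference data.frame with columns `class`, `id`, `sequence`.
#' @param seed_length Seed length for the exact prefix match (default 28).
#' @return List with `counts` (named integer incl. Undetermined),
#'   `percentages`, and `reference` (the deduplicated reference used).
#' @export
classify_rna_classes <- function(sequences, reference, seed_length = 28L) {
  stopifnot(all(c("class", "id", "sequence") %in% names(reference)))
  if (nrow(reference) == 0) stop("empty class reference")
  mirna_seqs <- reference$sequence[reference$class == "miRNA"]
  drop <- reference$class == "piRNA" & reference$sequence %in% mirna_seqs
  reference <- reference[!drop, , drop = FALSE]

  classes <- unique(reference$class)
  assigned <- rep("Undetermined", length(sequences))
  seed <- substr(sequences, 1L, pmin(seed_length, nchar(sequences)))
  pending <- seq_along(sequences)
  for (cl in classes) {
    if (length(pending) == 0L) break
    entries <- reference$sequence[reference$class == cl]
    hit <- vapply(seed[pending], function(s)
      any(grepl(s, entries, fixed = TRUE)), logical(1), USE.NAMES = FALSE)
    assigned[pending[hit]] <- cl
    pending <- pending[!hit]
  }
  counts <- table(factor(assigned, levels = c(classes, "Undetermined")))
  counts <- stats::setNames(as.integer(counts), names(counts))
  list(counts = counts,
       percentages = 100 * counts / max(1L, length(sequences)),
       reference = reference)
}
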