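#' Trimming configuration
#'
#' Kit-aware trimming settings. The minimum insert length defaults to 16
#' in synthetic-pool mode (the shortest synthetic reference) and should be
#' 18 for biological libraries, where true miRNAs are generally longer.
#'
#' @param layout Kit layout: `"nextflex"`, `"clontech"` or `"plain"`.
#' @param adapter3 3' adapter sequence (required for nextflex/plain).
#' @param min_length Minimum retained insert length.
#' @param min_overlap Minimum adapter-prefix overlap for a trim hit.
#' @param polyA_min_run Minimum adenine run marking the clontech 3' end.
#' @param umi_len Degenerate bases per adapter end (nextflex).
#' @return A `trim_config` list.
#' @export
trim_config <- function(layout = c("nextflex", "clontech", "plain"),
                        adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                        min_length = 16L, min_overlap = 5L,
                        polyA_min_run = 10L, umi_len = 4L) {
  layout <- match.arg(layout)
  if (min_length < 1) stop("min_length must be >= 1")
  if (layout != "clontech" && (is.null(adapter3) || !nzchar(adapter3)))
    stop("adapter3 must be non-empty for nextflex/plain layouts")
  structure(list(layout = layout, adapter3 = adapter3,
                 min_length = as.integer(min_length),
                 min_overlap = as.integer(min_overlap),
                 polyA_min_run = as.integer(polyA_min_run),
                 umi_len = as.integer(umi_len)),
            class = "trim_config")
}

#' Trim the 3' adapter from reads
#'
#' Locates, for each read, the leftmost occurrence of the adapter — either
#' the full adapter internally, or an adapter prefix of at least
#' `min_overlap` bases running to the read's 3' end — and removes it
#' together with everything 3' of it. Matching is exact (no error
#' tolerance), which keeps the stage deterministic. Reads without a hit
#' are returned unchanged.
#'
#' @param sequences Character vector of read sequences.
#' @param adapter3 Adapter sequence.
#' @param min_overlap Minimum prefix overlap (>= 3).
#' @return Character vector of trimmed sequences (possibly empty strings).
#' @examples
#' trim_3prime_adapter("ACGTACGTTGGAATTCTCGG", "TGGAATTCTCGG") # "ACGTACGT"
#' @export
trim_3prime_adapter <- function(sequences, adapter3, min_overlap = 5L) {
  if (min_overlap < 3L) stop("min_overlap must be >= 3")
  n <- length(sequences)
  if (n == 0L) return(character(0))
  alen <- nchar(adapter3)
  len <- nchar(sequences)

  # leftmost internal occurrence of the full adapter
  cut_at <- regexpr(adapter3, sequences, fixed = TRUE)
  cut_at[cut_at == -1L] <- NA_integer_

  # suffix overlaps with an adapter prefix (longest first = leftmost start)
  unresolved <- seq_len(n)
  k_hi <- min(alen, max(len))
  ks <- if (k_hi >= min_overlap) seq.int(k_hi, min_overlap) else integer(0)
  for (k in ks) {
    if (length(unresolved) == 0L) break
    pref <- substr(adapter3, 1L, k)
    i <- unresolved[len[unresolved] >= k]
    if (length(i) == 0L) next
    hit <- substr(sequences[i], len[i] - k + 1L, len[i]) == pref
    pos <- len[i][hit] - k + 1L
    j <- i[hit]
    better <- is.na(cut_at[j]) | pos < cut_at[j]
    cut_at[j[better]] <- pos[better]
    unresolved <- setdiff(unresolved, j)
  }

  out <- sequences
  found <- !is.na(cut_at)
  out[found] <- substr(sequences[found], 1L, cut_at[found] - 1L)
  out
}

#' Extract the 4+4 UMI from adapter-trimmed nextflex reads
#'
#' After adapter removal, the first and last four bases of a nextflex read
#' are the degenerate adapter bases; their concatenation (first4 + last4)
#' is the 8-mer UMI, which is appended to the read identifier as an
#' underscore suffix. Reads whose UMI contains any base outside A/C/G/T
#' are removed, and reads too short to contain both UMI halves plus at
#' least one insert base are discarded.
#'
#' @param reads A `read_set` of adapter-trimmed reads.
#' @param umi_len Degenerate bases per end (default 4).
#' @return List with `reads` (inserts, UMI-suffixed ids, dialect
#'   `"underscore-suffix"`) and `tally` (named discard counts).
#' @export
extract_umi_nextflex <- function(reads, umi_len = 4L) {
  len <- nchar(reads$sequence)
  too_short <- len < 2L * umi_len + 1L
  umi <- paste0(substr(reads$sequence, 1L, umi_len),
                substr(reads$sequence, len - umi_len + 1L, len))
  bad_umi <- !too_short & grepl("[^ACGT]", umi)
  keep <- !too_short & !bad_umi

  ids <- reads$read_id[keep]
  out <- read_set(
    read_id = if (length(ids)) paste0(ids, "_", umi[keep]) else character(0),
    sequence = substr(reads$sequence[keep], umi_len + 1L,
                      len[keep] - umi_len),
    quality = substr(reads$quality[keep], umi_len + 1L,
                     len[keep] - umi_len),
    umi_dialect = "underscore-suffix")
  list(reads = out,
       tally = c(umi_too_short = sum(too_short),
                 umi_unknown_base = sum(bad_umi)))
}

#' Trim clontech (template-switch) reads
#'
#' Drops the first three bases (added by the template-switching method),
#' then truncates at the start of the leftmost run of at least
#' `polyA_min_run` consecutive adenines, removing the run and everything
#' 3' of it; reads without such a run are kept whole after the 5' trim.
#' The rule is applied literally, so a genuine adenine run inside the
#' insert also truncates — a known failure mode of poly-A chemistry.
#'
#' @param reads A `read_set`.
#' @param polyA_min_run Minimum adenine run length (default 10).
#' @return A `read_set` of inserts (possibly empty sequences; apply
#'   [length_filter()] next).
#' @export
trim_clontech <- function(reads, polyA_min_run = 10L) {
  seqs <- substr(reads$sequence, 4L, nchar(reads$sequence))
  quals <- substr(reads$quality, 4L, nchar(reads$quality))
  pat <- strrep("A", polyA_min_run)
  pos <- regexpr(pat, seqs, fixed = TRUE)
  hit <- pos != -1L
  seqs[hit] <- substr(seqs[hit], 1L, pos[hit] - 1L)
  quals[hit] <- substr(quals[hit], 1L, pos[hit] - 1L)
  read_set(reads$read_id, seqs, quals,
           umi_dialect = attr(reads, "umi_dialect"))
}

#' Filter reads by minimum insert length
#'
#' @param reads A `read_set`.
#' @param min_length Minimum retained insert length.
#' @return List with `reads` (retained) and `tally` (named counts:
#'   retained, too_short).
#' @export
length_filter <- function(reads, min_length = 16L) {
  keep <- nchar(reads$sequence) >= min_length
  out <- reads[keep, , drop = FALSE]
  attr(out, "umi_dialect") <- attr(reads, "umi_dialect")
  class(out) <- c("read_set", "data.frame")
  list(reads = out,
       tally = c(retained = sum(keep), too_short = sum(!keep)))
}

#' Kit-aware preprocessing: trim, extract UMIs, length-filter
#'
#' Dispatches on the configured layout: nextflex reads are adapter-trimmed,
#' then split into UMI and insert; clontech reads lose their template-switch
#' bases and poly-A tail; plain reads are adapter-trimmed only. All layouts
#' finish with the minimum-length filter. Every input read ends up exactly
#' once in either the retained set or the discard tally.
#'
#' @param reads A `read_set` of raw reads.
#' @param config A `trim_config`.
#' @return List with `reads` (retained inserts) and `tally` (named discard
#'   counts including `retained`).
#' @export
preprocess_reads <- function(reads, config) {
  stopifnot(inherits(config, "trim_config"))
  tally <- c()
  if (config$layout %in% c("nextflex", "plain")) {
    trimmed <- reads
    trimmed$sequence <- trim_3prime_adapter(reads$sequence, config$adapter3,
                                            config$min_overlap)
    trimmed$quality <- substr(reads$quality, 1L, nchar(trimmed$sequence))
    if (config$layout == "nextflex") {
      ex <- extract_umi_nextflex(trimmed, config$umi_len)
      trimmed <- ex$reads
      tally <- ex$tally
    }
  } else {
    trimmed <- trim_clontech(reads, config$polyA_min_run)
  }
  lf <- length_filter(trimmed, config$min_length)
  list(reads = lf$reads, tally = c(tally, lf$tally))
}
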