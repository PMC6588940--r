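#' Build a synthetic equimolar reference pool
#'
#' Generates a pool of unique random small-RNA sequences emulating a
#' commercial equimolar reference of synthetic miRNAs (the default size of
#' 962 matches the widely used universal miRNA reference pool). Sequences
#' are drawn uniformly over A/C/G/T, subject to a length window and a GC
#' window, and deduplicated; every entry receives molar fraction `1/n`.
#'
#' @param n Number of sequences (default 962).
#' @param length_range Integer vector `c(min, max)`, bounds inclusive;
#'   must lie within 16..30.
#' @param gc_range Numeric `c(min, max)` GC-fraction window.
#' @param seed Integer seed; the pool is deterministic given the seed.
#' @param source Label stored as pool metadata.
#' @return A `reference_pool`: data.frame with columns `id`, `sequence`,
#'   `molar_fraction`, and attribute `source`.
#' @examples
#' pool <- build_reference_pool(n = 10, seed = 1)
#' sum(pool$molar_fraction) # 1
#' @export
build_reference_pool <- function(n = 962, length_range = c(16, 28),
                                 gc_range = c(0.2, 0.8), seed = NULL,
                                 source = "synthetic-equimolar") {
  stopifnot(n >= 1, length(length_range) == 2, length(gc_range) == 2)
  lmin <- as.integer(length_range[1]); lmax <- as.integer(length_range[2])
  if (lmin < 16 || lmax > 30 || lmin > lmax)
    stop("length_range must lie within [16, 30] with min <= max")
  if (gc_range[1] > gc_range[2] || gc_range[1] < 0 || gc_range[2] > 1)
    stop("gc_range must be an increasing window within [0, 1]")

  # capacity of the constrained sequence space at the least permissive length
  capacity <- function(L) {
    k <- seq.int(ceiling(gc_range[1] * L), floor(gc_range[2] * L))
    k <- k[k >= 0 & k <= L]
    if (length(k) == 0) return(0)
    sum(choose(L, k)) * 2^L / 2^0 # C(L,k) GC placements x 2^k x 2^(L-k) = C(L,k) 2^L
  }
  total_capacity <- sum(vapply(lmin:lmax, capacity, numeric(1)))
  if (total_capacity < n)
    stop(sprintf(
      "cannot draw %.0f unique sequences: only %.3g sequences satisfy lengths [%d,%d] and GC [%g,%g]",
      n, total_capacity, lmin, lmax, gc_range[1], gc_range[2]))

  maybe_set_seed(seed)
  sequences <- character(0)
  attempts <- 0L
  while (length(sequences) < n) {
    attempts <- attempts + 1L
    if (attempts > 1000L)
      stop("failed to generate enough unique sequences within the GC window; widen gc_range or length_range")
    need <- n - length(sequences)
    widths <- if (lmin == lmax) rep(lmin, 2L * need + 10L)
      else sample(lmin:lmax, size = 2L * need + 10L, replace = TRUE)
    cand <- vapply(widths, function(w)
      paste(sample(BASES, w, replace = TRUE), collapse = ""), character(1))
    gc <- gc_fraction(cand)
    cand <- cand[gc >= gc_range[1] & gc <= gc_range[2]]
    sequences <- unique(c(sequences, cand))
  }
  sequences <- sequences[seq_len(n)]

  pool <- data.frame(
    id = sprintf("synth-%04d", seq_len(n)),
    sequence = sequences,
    molar_fraction = rep(1 / n, n),
    stringsAsFactors = FALSE
  )
  attr(pool, "source") <- source
  class(pool) <- c("reference_pool", "data.frame")
  validate_reference_pool(pool)
  pool
}

#' Validate reference-pool invariants
#'
#' Checks unique ids and sequences, the 16-30 nt length window, and that
#' molar fractions sum to one.
#'
#' @param pool A `reference_pool`.
#' @return The pool, invisibly; stops on violation.
#' @export
validate_reference_pool <- function(pool) {
  stopifnot(is.data.frame(pool),
            all(c("id", "sequence", "molar_fraction") %in% names(pool)))
  if (anyDuplicated(pool$id)) stop("reference pool ids must be unique")
  if (anyDuplicated(pool$sequence)) stop("reference pool sequences must be unique")
  w <- nchar(pool$sequence)
  if (any(w < 16 | w > 30)) stop("reference sequences must be 16-30 nt")
  if (any(grepl("[^ACGT]", pool$sequence)))
    stop("reference sequences must be over the A/C/G/T alphabet")
  if (any(pool$molar_fraction <= 0 | pool$molar_fraction > 1))
    stop("molar fractions must be in (0, 1]")
  if (abs(sum(pool$molar_fraction) - 1) > 1e-9)
    stop("molar fractions must sum to 1")
  invisible(pool)
}

#' Re-weight a pool with skewed (non-equimolar) abundances
#'
#' Replaces the uniform molar fractions with log-normal draws, emulating a
#' biological small-RNA abundance distribution spanning several orders of
#' magnitude; used by the pipeline's biological-mode arm.
#'
#' @param pool A `reference_pool`.
#' @param sdlog Log-normal shape parameter (natural-log scale).
#' @param seed Integer seed.
#' @return The pool with rescaled `molar_fraction` (sums to 1).
#' @export
skew_pool <- function(pool, sdlog = 1.5, seed = NULL) {
  validate_reference_pool(pool)
  maybe_set_seed(seed)
  w <- stats::rlnorm(nrow(pool), meanlog = 0, sdlog = sdlog)
  pool$molar_fraction <- w / sum(w)
  validate_reference_pool(pool)
}

#' Write a reference pool to FASTA
#' @param pool A `reference_pool`.
#' @param path Output FASTA path.
#' @return `path`, invisibly.
#' @export
write_pool_fasta <- function(pool, path) {
  validate_reference_pool(pool)
  x <- Biostrings::DNAStringSet(pool$sequence)
  names(x) <- pool$id
  Biostrings::writeXStringSet(x, filepath = path, format = "fasta")
  invisible(path)
}

#' Read a reference pool from FASTA
#'
#' Molar fractions are uniform unless the FASTA headers carry a
#' `molar_fraction=` tag.
#'
#' @param path FASTA path.
#' @return A `reference_pool`.
#' @export
read_pool_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path, format = "fasta")
  ids <- sub("\\s.*$", "", names(x))
  frac <- rep(1 / length(x), length(x))
  tagged <- grepl("molar_fraction=", names(x))
  if (any(tagged))
    frac[tagged] <- as.numeric(sub(".*molar_fraction=([0-9.eE+-]+).*", "\\1",
                                   names(x)[tagged]))
  pool <- data.frame(id = ids, sequence = as.character(x),
                     molar_fraction = frac / sum(frac),
                     stringsAsFactors = FALSE)
  attr(pool, "source") <- path
  class(pool) <- c("reference_pool", "data.frame")
  validate_reference_pool(pool)
  pool
}
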