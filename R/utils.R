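#' @keywords internal
"_PACKAGE"

BASES <- c("A", "C", "G", "T")

# set.seed only when the caller supplied one; NULL means "continue the
# current RNG stream" so wrappers can drive several stages from one seed.
maybe_set_seed <- function(seed) {
  if (!is.null(seed)) {
    stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
    set.seed(as.integer(seed))
  }
  invisible(NULL)
}

#' Number of distinct UMI labels for a degenerate-base design
#'
#' A UMI composed of `len_each_end` random bases on each adapter end draws
#' from `4^(2 * len_each_end)` equally likely labels; the default 4+4 design
#' yields 65,536.
#'
#' @param len_each_end Number of degenerate bases on each adapter end.
#' @return Number of distinct UMI labels.
#' @examples
#' umi_space_size(4) # 65536
#' @export
umi_space_size <- function(len_each_end = 4) {
  stopifnot(len_each_end >= 0)
  4^(2 * len_each_end)
}

# fraction of G/C bases, vectorised over sequences
gc_fraction <- function(sequences) {
  n <- nchar(sequences)
  gc <- nchar(gsub("[AT]", "", sequences))
  ifelse(n > 0, gc / n, 0)
}

# vectorised random DNA strings
random_dna <- function(n, width) {
  if (n == 0L) return(character(0))
  mat <- matrix(sample(BASES, n * width, replace = TRUE), nrow = n)
  do.call(paste0, as.data.frame(mat, stringsAsFactors = FALSE))
}

# Hamming distance between two equal-length strings
hamming <- function(a, b) {
  if (nchar(a) != nchar(b)) stop("Hamming distance requires equal lengths")
  sum(utf8ToInt(a) != utf8ToInt(b))
}

# expected number of distinct labels when m balls fall into U boxes
expected_distinct_umis <- function(m, U) {
  U * (1 - (1 - 1 / U)^m)
}

# position (1-based) and length of the first homopolymer run of at least
# min_run identical bases; NA if none
first_homopolymer_run <- function(sequence, min_run = 4L) {
  m <- regexpr(sprintf("([ACGT])\\1{%d,}", min_run - 1L), sequence, perl = TRUE)
  if (m == -1L) return(NULL)
  list(start = as.integer(m), length = attr(m, "match.length"))
}
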