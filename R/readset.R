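#' Construct a read set
#'
#' A read set is a data.frame of single-end reads (`read_id`, `sequence`,
#' `quality`) with an `umi_dialect` attribute recording whether UMIs are
#' carried as an underscore suffix on the read identifier.
#'
#' @param read_id,sequence,quality Parallel character vectors.
#' @param umi_dialect `"none"` or `"underscore-suffix"`.
#' @return A `read_set`.
#' @export
read_set <- function(read_id, sequence, quality = NULL,
                     umi_dialect = "none") {
  if (is.null(quality)) quality <- strrep("I", nchar(sequence))
  if (any(nchar(sequence) != nchar(quality)))
    stop("sequence and quality lengths must match")
  out <- data.frame(read_id = read_id, sequence = sequence,
                    quality = quality, stringsAsFactors = FALSE)
  attr(out, "umi_dialect") <- match.arg(umi_dialect,
                                        c("none", "underscore-suffix"))
  class(out) <- c("read_set", "data.frame")
  out
}

#' Write a read set as FASTQ
#' @param reads A `read_set`.
#' @param path Output path (`.gz` suffix gzips).
#' @return `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  x <- Biostrings::DNAStringSet(reads$sequence)
  names(x) <- reads$read_id
  Biostrings::writeXStringSet(
    x, filepath = path, format = "fastq",
    qualities = Biostrings::BStringSet(reads$quality),
    compress = grepl("\\.gz$", path))
  invisible(path)
}

#' Read a FASTQ file into a read set
#' @param path FASTQ path (gzip ok).
#' @param umi_dialect Declared UMI dialect of the identifiers.
#' @return A `read_set`.
#' @export
read_fastq <- function(path, umi_dialect = "none") {
  x <- Biostrings::readDNAStringSet(path, format = "fastq",
                                    with.qualities = TRUE)
  read_set(read_id = sub("\\s.*$", "", names(x)),
           sequence = as.character(x),
           quality = as.character(S4Vectors::mcols(x)$qualities),
           umi_dialect = umi_dialect)
}
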