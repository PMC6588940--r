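#' Sample pre-amplification molecules from a pool
#'
#' Draws the true pre-PCR molecule population: a multinomial draw of
#' `total_molecules` molecules over `molar_fraction * weight`
#' (renormalized), with an independent uniform UMI attached to each
#' molecule. UMIs are attached here — before reverse transcription and
#' amplification — matching degenerate-adapter chemistry where the adapters
#' (and their random bases) are ligated first; all PCR copies of a molecule
#' inherit its UMI exactly.
#'
#' @param pool A `reference_pool`.
#' @param weights Named per-id selection weights (see [selection_weights()]).
#' @param total_molecules Total molecules to draw (>= 1).
#' @param umi_length_each_end Degenerate bases per adapter end (4 for the
#'   nextflex layout, 0 for UMI-free chemistries); the combined UMI is the
#'   concatenation of both ends, giving `4^(2*len)` possible labels.
#' @param seed Integer seed or `NULL` to continue the current RNG stream.
#' @return List with `molecules` (data.frame: `molecule_id`, `parent_id`,
#'   `sequence`, `umi`, `is_artifact`, `artifact_kind`, `count`) and
#'   `truth` (a `truth_table` with the per-reference molecule counts).
#' @export
sample_molecules <- function(pool, weights, total_molecules,
                             umi_length_each_end = 4L, seed = NULL) {
  validate_reference_pool(pool)
  stopifnot(total_molecules >= 1, umi_length_each_end >= 0)
  if (!all(pool$id %in% names(weights)))
    stop("weights must cover every pool id")
  maybe_set_seed(seed)

  p <- pool$molar_fraction * weights[pool$id]
  p <- p / sum(p)
  counts <- as.vector(stats::rmultinom(1, size = total_molecules, prob = p))

  parent <- rep(pool$id, counts)
  seqs <- rep(pool$sequence, counts)
  n <- length(parent)
  umi <- if (umi_length_each_end > 0)
    random_dna(n, 2L * umi_length_each_end) else rep("", n)

  molecules <- data.frame(
    molecule_id = sprintf("m%07d", seq_len(n)),
    parent_id = parent,
    sequence = seqs,
    umi = umi,
    is_artifact = rep(FALSE, n),
    artifact_kind = rep("", n),
    count = rep(1L, n),
    stringsAsFactors = FALSE
  )

  truth <- list(
    per_reference = data.frame(id = pool$id,
                               true_molecules_pre_pcr = counts,
                               stringsAsFactors = FALSE),
    reads = NULL,
    artifact_ledger = data.frame(parent_id = character(0),
                                 kind = character(0), count = integer(0),
                                 stringsAsFactors = FALSE),
    total_molecules = total_molecules
  )
  class(truth) <- "truth_table"
  list(molecules = molecules, truth = truth)
}

#' Inject isomiR-generating library artifacts
#'
#' Applies independent per-molecule artifact events before amplification:
#' 3' trimming by 1-2 nt and 3' non-templated addition of 1-2 nt from
#' \{A,T\} (any layout), and — only for the template-switch (clontech)
#' layout — 5' truncation by 1-3 nt (strand invasion) and 5' extension by
#' 1-3 nt (template-switch oligo concatamers). Altered molecules are
#' flagged and every fired event is recorded in the artifact ledger
#' attached as `attr(, "artifact_ledger")`.
#'
#' @param molecules Molecule data.frame from [sample_molecules()].
#' @param model A `bias_model` (supplies `artifact_rates` and the layout).
#' @param seed Integer seed or `NULL`.
#' @return The molecule data.frame with modified sequences and artifact
#'   flags, plus an `artifact_ledger` attribute (data.frame with
#'   `parent_id`, `kind`, `count`).
#' @export
inject_isomir_artifacts <- function(molecules, model, seed = NULL) {
  maybe_set_seed(seed)
  n <- nrow(molecules)
  rates <- model$artifact_rates
  clontech <- model$kit_layout == "clontech"

  events <- list(
    strand_invasion5 = if (clontech) stats::runif(n) < rates[["strand_invasion5"]] else rep(FALSE, n),
    concatamer5 = if (clontech) stats::runif(n) < rates[["concatamer5"]] else rep(FALSE, n),
    trim3 = stats::runif(n) < rates[["trim3"]],
    ext3 = stats::runif(n) < rates[["ext3"]]
  )

  seqs <- molecules$sequence
  kinds <- molecules$artifact_kind

  idx <- which(events$strand_invasion5)
  if (length(idx)) {
    k <- sample(1:3, length(idx), replace = TRUE)
    seqs[idx] <- substr(seqs[idx], k + 1L, nchar(seqs[idx]))
  }
  idx <- which(events$concatamer5)
  if (length(idx)) {
    k <- sample(1:3, length(idx), replace = TRUE)
    ext <- substr(random_dna(length(idx), 3L), 1L, k)
    seqs[idx] <- paste0(ext, seqs[idx])
  }
  idx <- which(events$trim3)
  if (length(idx)) {
    k <- sample(1:2, length(idx), replace = TRUE)
    seqs[idx] <- substr(seqs[idx], 1L, pmax(1L, nchar(seqs[idx]) - k))
  }
  idx <- which(events$ext3)
  if (length(idx)) {
    k <- sample(1:2, length(idx), replace = TRUE)
    add <- vapply(k, function(m)
      paste(sample(c("A", "T"), m, replace = TRUE), collapse = ""),
      character(1))
    seqs[idx] <- paste0(seqs[idx], add)
  }

  fired <- Reduce(`|`, events)
  altered <- fired & (seqs != molecules$sequence)
  for (kind in names(events)) {
    hit <- events[[kind]] & altered
    kinds[hit] <- ifelse(kinds[hit] == "", kind, paste(kinds[hit], kind, sep = "+"))
  }
  molecules$sequence <- seqs
  molecules$is_artifact <- molecules$is_artifact | altered
  molecules$artifact_kind <- kinds

  ledger <- do.call(rbind, lapply(names(events), function(kind) {
    hit <- events[[kind]] & altered
    if (!any(hit)) return(NULL)
    agg <- table(molecules$parent_id[hit])
    data.frame(parent_id = names(agg), kind = kind,
               count = as.integer(agg), stringsAsFactors = FALSE)
  }))
  if (is.null(ledger))
    ledger <- data.frame(parent_id = character(0), kind = character(0),
                         count = integer(0), stringsAsFactors = FALSE)
  attr(molecules, "artifact_ledger") <- ledger
  molecules
}

#' PCR-amplify a molecule population
#'
#' Runs `pcr_cycles` rounds of stochastic duplication. In each cycle every
#' molecule copy spawns one new copy with probability
#' `e_i = pcr_efficiency_base + pcr_efficiency_gc_coeff * (GC_i - 0.5)`
#' (clamped to (0, 1\]); copies inherit the parent molecule's UMI and
#' lineage. With probability `stutter_prob` a new copy of a sequence
#' containing a homopolymer run of length >= 4 contracts or expands that
#' run by one base (fair coin). The expected family size of a molecule is
#' `(1 + e_i)^cycles`. Identical copies are tracked as per-lineage counts,
#' which is distributionally equivalent to simulating each copy event
#' individually (copies within a lineage are exchangeable; stuttered
#' copies branch into their own lineage rows).
#'
#' @param molecules Molecule data.frame (a `count` column is honoured).
#' @param model A `bias_model`.
#' @param seed Integer seed or `NULL`.
#' @return Molecule data.frame with updated `count` (one row per distinct
#'   lineage/sequence combination).
#' @export
amplify <- function(molecules, model, seed = NULL) {
  maybe_set_seed(seed)
  if (model$pcr_cycles == 0L) return(molecules)
  if (is.null(molecules$count)) molecules$count <- 1L

  for (cycle in seq_len(model$pcr_cycles)) {
    gc <- gc_fraction(molecules$sequence)
    e <- pcr_efficiency(model, gc)
    new_copies <- stats::rbinom(nrow(molecules), molecules$count, e)
    if (model$stutter_prob > 0) {
      # stutter only acts where a run of >= 4 identical bases exists
      uniq <- unique(molecules$sequence)
      has_run <- vapply(uniq, function(s)
        !is.null(first_homopolymer_run(s)), logical(1))
      eligible <- has_run[match(molecules$sequence, uniq)]
      stuttered <- ifelse(eligible,
                          stats::rbinom(nrow(molecules), new_copies,
                                        model$stutter_prob), 0L)
    } else {
      stuttered <- rep(0L, nrow(molecules))
    }
    molecules$count <- molecules$count + new_copies - stuttered

    idx <- which(stuttered > 0L)
    if (length(idx)) {
      contract <- stats::rbinom(length(idx), stuttered[idx], 0.5)
      expand <- stuttered[idx] - contract
      mutate_run <- function(s, delta) {
        run <- first_homopolymer_run(s)
        base <- substr(s, run$start, run$start)
        new_len <- max(1L, run$length + delta)
        paste0(substr(s, 1L, run$start - 1L),
               strrep(base, new_len),
               substr(s, run$start + run$length, nchar(s)))
      }
      extra <- do.call(rbind, lapply(seq_along(idx), function(j) {
        i <- idx[j]
        rows <- list()
        for (variant in c(-1L, 1L)) {
          m <- if (variant == -1L) contract[j] else expand[j]
          if (m == 0L) next
          row <- molecules[i, , drop = FALSE]
          row$sequence <- mutate_run(row$sequence, variant)
          row$count <- m
          row$is_artifact <- TRUE
          row$artifact_kind <- ifelse(row$artifact_kind == "", "stutter",
                                      paste(row$artifact_kind, "stutter", sep = "+"))
          rows[[length(rows) + 1L]] <- row
        }
        if (length(rows)) do.call(rbind, rows) else NULL
      }))
      if (!is.null(extra)) molecules <- rbind(molecules, extra)
    }
  }
  rownames(molecules) <- NULL
  molecules
}

# fixed bases contributed by the template-switching oligo in clontech reads
CLONTECH_TS_BASES <- "GGG"
CLONTECH_POLYA_RUN <- 15L

#' Sequence a molecule population into reads
#'
#' Constructs one single-end read per molecule copy under the kit layout:
#' nextflex reads are `[5' UMI 4 nt][insert][3' UMI 4 nt][3' adapter...]`,
#' clontech reads are `[3 template-switch bases][insert][poly-A run...]`,
#' plain reads are `[insert][3' adapter...]`; all are truncated or padded
#' to `read_length` (default 51 nt). Independent per-base substitution
#' errors at `seq_error_rate` are applied to the whole read, UMI bases
#' included. Qualities are a constant character (Q40 by default).
#'
#' @param molecules Amplified molecule data.frame (with `count`).
#' @param model A `bias_model`.
#' @param read_length Machine read length (default 51).
#' @param seed Integer seed or `NULL`.
#' @param quality_char Constant quality character for all bases.
#' @param truth A `truth_table` to complete with per-read records, or
#'   `NULL` to build a fresh one.
#' @return List with `reads` (a `read_set` data.frame: `read_id`,
#'   `sequence`, `quality`) and `truth` (the `truth_table` with per-read
#'   `read_id`, `parent_id`, `umi`, `is_artifact`, `artifact_kind`,
#'   `true_insert`).
#' @export
sequence_reads <- function(molecules, model, read_length = 51L, seed = NULL,
                           quality_char = "I", truth = NULL) {
  maybe_set_seed(seed)
  if (is.null(molecules$count)) molecules$count <- 1L
  idx <- rep(seq_len(nrow(molecules)), molecules$count)
  n <- length(idx)
  insert <- molecules$sequence[idx]
  umi <- molecules$umi[idx]

  core <- switch(model$kit_layout,
    nextflex = paste0(substr(umi, 1, 4), insert, substr(umi, 5, 8),
                      model$adapter3),
    clontech = paste0(CLONTECH_TS_BASES, insert,
                      strrep("A", CLONTECH_POLYA_RUN)),
    plain = paste0(insert, model$adapter3),
    stop("unknown kit layout: ", model$kit_layout)
  )
  pad_char <- if (model$kit_layout == "clontech") "A" else "A"
  short <- nchar(core) < read_length
  if (any(short))
    core[short] <- paste0(core[short],
                          strrep(pad_char, read_length - nchar(core[short])))
  reads <- substr(core, 1L, read_length)

  if (model$seq_error_rate > 0) {
    n_err <- stats::rbinom(n, read_length, model$seq_error_rate)
    hit <- which(n_err > 0L)
    for (i in hit) {
      pos <- sample.int(read_length, n_err[i])
      chars <- strsplit(reads[i], "")[[1]]
      for (p in pos) chars[p] <- sample(setdiff(BASES, chars[p]), 1L)
      reads[i] <- paste(chars, collapse = "")
    }
  }

  read_id <- sprintf("read%08d", seq_len(n))
  read_set <- data.frame(read_id = read_id, sequence = reads,
                         quality = strrep(quality_char, read_length),
                         stringsAsFactors = FALSE)
  attr(read_set, "umi_dialect") <- "none"
  class(read_set) <- c("read_set", "data.frame")

  if (is.null(truth)) {
    truth <- list(per_reference = NULL, reads = NULL,
                  artifact_ledger = attr(molecules, "artifact_ledger"),
                  total_molecules = NA_integer_)
    class(truth) <- "truth_table"
  }
  truth$reads <- data.frame(
    read_id = read_id,
    parent_id = molecules$parent_id[idx],
    umi = umi,
    molecule_id = molecules$molecule_id[idx],
    is_artifact = molecules$is_artifact[idx],
    artifact_kind = molecules$artifact_kind[idx],
    true_insert = insert,
    stringsAsFactors = FALSE
  )
  list(reads = read_set, truth = truth)
}

#' Simulate a complete small-RNA library with ground truth
#'
#' End-to-end generator: selection weights, multinomial molecule sampling
#' with UMI tagging, artifact injection, PCR amplification with stutter,
#' and sequencing with per-base error — returning the FASTQ-ready reads
#' and a complete ground-truth table (per-reference molecule counts,
#' per-read parent/UMI assignments, artifact ledger). Byte-identical
#' output for identical configuration and seed.
#'
#' @param pool A `reference_pool`.
#' @param model A `bias_model`.
#' @param total_molecules Pre-PCR molecules to draw.
#' @param seed Integer seed (drives every random stage).
#' @param read_length Machine read length (default 51).
#' @param fold_energies Optional named fold-energy table for the
#'   structure bias term.
#' @return List with `reads` (a `read_set`) and `truth` (a `truth_table`).
#' @examples
#' pool <- build_reference_pool(n = 20, seed = 1)
#' sim <- simulate_library(pool, bias_model(pcr_cycles = 0),
#'                         total_molecules = 500, seed = 42)
#' nchar(sim$reads$sequence[1]) # 51
#' @export
simulate_library <- function(pool, model, total_molecules, seed,
                             read_length = 51L, fold_energies = NULL) {
  maybe_set_seed(seed)
  w <- selection_weights(pool, model, fold_energies)
  sm <- sample_molecules(pool, w, total_molecules,
                         umi_length_each_end = model$umi_len, seed = NULL)
  mol <- inject_isomir_artifacts(sm$molecules, model, seed = NULL)
  sm$truth$artifact_ledger <- attr(mol, "artifact_ledger")
  amp <- amplify(mol, model, seed = NULL)
  attr(amp, "artifact_ledger") <- attr(mol, "artifact_ledger")
  sequence_reads(amp, model, read_length = read_length, seed = NULL,
                 truth = sm$truth)
}
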