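#' Illustrative per-kit simulator profiles
#'
#' One bias-model parameterization per emulated library-preparation
#' method. The profiles are qualitative: ligation-based fixed-adapter
#' chemistries ("illumina-like", "neb-like") carry strong terminal
#' dinucleotide ligation bias; the degenerate-adapter chemistry
#' ("nextflex") carries much weaker ligation bias and activates 4+4 UMI
#' tagging; the template-switch chemistry ("clontech") is ligation-free
#' but prone to 5' strand-invasion and oligo-concatamer artifacts. The
#' ligation log-weights are order-of-magnitude illustrations (within
#' \[-1, 1\]), not fitted values. All profiles share GC-dependent PCR
#' efficiency and a low 3' trim/extension artifact floor.
#'
#' @param pcr_cycles Cycles used by every profile (scaled down from
#'   bench protocols to keep simulated depth manageable).
#' @param seq_error_rate Per-base sequencing error.
#' @return Named list of `bias_model` objects.
#' @export
method_profiles <- function(pcr_cycles = 4, seq_error_rate = 0.001) {
  lig_strong <- c(GG = 0.8, GC = 0.5, CC = 0.4, AT = -0.6, TT = -0.8, AA = -0.5)
  lig_mild <- lig_strong / 4
  base <- list(pcr_efficiency_base = 0.625, pcr_efficiency_gc_coeff = 0.2,
               pcr_cycles = pcr_cycles, seq_error_rate = seq_error_rate)
  common_artifacts <- c(trim3 = 0.01, ext3 = 0.01)
  list(
    `illumina-like` = do.call(bias_model, c(base, list(
      kit_layout = "plain", lig5_weights = lig_strong,
      lig3_weights = lig_strong, artifact_rates = common_artifacts))),
    `neb-like` = do.call(bias_model, c(base, list(
      kit_layout = "plain", lig5_weights = lig_strong / 2,
      lig3_weights = lig_strong / 2, artifact_rates = common_artifacts))),
    nextflex = do.call(bias_model, c(base, list(
      kit_layout = "nextflex", lig5_weights = lig_mild,
      lig3_weights = lig_mild, artifact_rates = common_artifacts))),
    clontech = do.call(bias_model, c(base, list(
      kit_layout = "clontech",
      artifact_rates = c(common_artifacts,
                         strand_invasion5 = 0.08, concatamer5 = 0.04))))
  )
}

#' Assemble a pipeline configuration
#'
#' @param out_dir Output directory.
#' @param seed Global seed; every sample derives its own stream from it.
#' @param design data.frame with columns `sample`, `method` (one of
#'   clontech, illumina-like, neb-like, nextflex, deduped, fivepercent),
#'   `input_ng`, `batch`, `replicate`. Input amount scales the molecule
#'   count; batches additionally apply a small multiplicative depth
#'   jitter and their own seed offset.
#' @param pool_n Reference-pool size.
#' @param pool_skew `NULL` for an equimolar pool, or a log-normal `sdlog`
#'   for a skewed (biological-mode) pool.
#' @param molecules_per_ng Pre-PCR molecules drawn per ng of input.
#' @param read_length Machine read length.
#' @param min_length Minimum insert length after trimming.
#' @param fivepercent_fraction Subsampling fraction of the control.
#' @param profiles Named list of `bias_model`s (see [method_profiles()]).
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(out_dir = tempfile("srnabench_run_"),
                            seed = 1L,
                            design = default_design(),
                            pool_n = 120L,
                            pool_skew = NULL,
                            molecules_per_ng = 10L,
                            read_length = 51L,
                            min_length = 16L,
                            fivepercent_fraction = 0.05,
                            profiles = method_profiles()) {
  structure(list(out_dir = out_dir, seed = as.integer(seed), design = design,
                 pool_n = pool_n, pool_skew = pool_skew,
                 molecules_per_ng = molecules_per_ng,
                 read_length = read_length, min_length = min_length,
                 fivepercent_fraction = fivepercent_fraction,
                 profiles = profiles),
            class = "pipeline_config")
}

#' Default demo design: four kits x triplicates, plus derived methods
#'
#' Triplicates of one input amount per method, with the UMI-collapsed
#' ("deduped") and 5%-subsample ("fivepercent") methods derived from each
#' nextflex sample.
#'
#' @param input_ng Input amount label.
#' @param batch Batch label.
#' @return Design data.frame.
#' @export
default_design <- function(input_ng = 300, batch = 1L) {
  methods <- c("illumina-like", "neb-like", "nextflex", "clontech",
               "deduped", "fivepercent")
  do.call(rbind, lapply(methods, function(m)
    data.frame(sample = sprintf("%s_rep%d", m, 1:3), method = m,
               input_ng = input_ng, batch = batch, replicate = 1:3,
               stringsAsFactors = FALSE)))
}

#' Validate a pipeline configuration
#'
#' @param config A `pipeline_config`.
#' @return Character vector of violated invariants (empty when valid).
#' @export
validate_config <- function(config) {
  errors <- character(0)
  d <- config$design
  need <- c("sample", "method", "input_ng", "batch", "replicate")
  if (!is.data.frame(d) || !all(need %in% names(d)))
    return(sprintf("design must be a data.frame with columns %s",
                   paste(need, collapse = ", ")))
  if (anyDuplicated(d$sample))
    errors <- c(errors, "duplicate sample names in design")
  known <- c(names(config$profiles), "deduped", "fivepercent")
  bad <- setdiff(unique(d$method), known)
  if (length(bad))
    errors <- c(errors, paste("unknown methods:", paste(bad, collapse = ", ")))
  derived <- d[d$method %in% c("deduped", "fivepercent"), , drop = FALSE]
  if (nrow(derived)) {
    nx <- d[d$method == "nextflex", , drop = FALSE]
    for (i in seq_len(nrow(derived))) {
      ok <- any(nx$input_ng == derived$input_ng[i] &
                nx$batch == derived$batch[i] &
                nx$replicate == derived$replicate[i])
      if (!ok)
        errors <- c(errors, sprintf(
          "sample '%s' (%s) has no nextflex parent with matching input/batch/replicate",
          derived$sample[i], derived$method[i]))
    }
  }
  if (!is.numeric(config$read_length) || config$read_length < 20)
    errors <- c(errors, "read_length must be a number >= 20")
  if (!is.numeric(config$molecules_per_ng) || config$molecules_per_ng < 1)
    errors <- c(errors, "molecules_per_ng must be >= 1")
  if (config$fivepercent_fraction <= 0 || config$fivepercent_fraction > 1)
    errors <- c(errors, "fivepercent_fraction must be in (0, 1]")
  errors
}

#' Run the full simulate-trim-quantify-dedup-metrics pipeline
#'
#' Simulates every primary design sample under its method profile, trims
#' and quantifies it, derives the deduped (directional UMI collapse of
#' the matching nextflex sample) and fivepercent (random subsample)
#' methods, normalizes all samples jointly by median-of-ratios, and
#' computes the metric suite: per-sample accuracy error, per-method
#' detection sets and inconsistency, false-isomiR summaries, per-method
#' triplicate error, top-20 abundance overlap, and the per-method
#' decomposition of accuracy error into sequence characteristics. All
#' tabular outputs are written under `config$out_dir` together with a
#' checksum manifest; a rerun with the same config and seed reproduces
#' them byte-identically.
#'
#' @param config A `pipeline_config`.
#' @param write_fastq_files Also write per-sample FASTQ (off by default to
#'   keep demo runs light).
#' @return Invisible report bundle: list with `counts`, `normalized`,
#'   `metrics`, `variance`, `tallies`, `manifest`, `pool`.
#' @export
run_pipeline <- function(config, write_fastq_files = FALSE) {
  errors <- validate_config(config)
  if (length(errors))
    stop("invalid pipeline config:\n  - ", paste(errors, collapse = "\n  - "))
  dir.create(config$out_dir, recursive = TRUE, showWarnings = FALSE)

  pool <- build_reference_pool(n = config$pool_n, seed = config$seed)
  if (!is.null(config$pool_skew))
    pool <- skew_pool(pool, sdlog = config$pool_skew,
                      seed = config$seed + 1L)
  write_pool_fasta(pool, file.path(config$out_dir, "reference_pool.fasta"))

  d <- config$design
  primary <- d[!d$method %in% c("deduped", "fivepercent"), , drop = FALSE]
  sims <- list(); processed <- list(); assignments <- list(); tallies <- list()

  for (i in seq_len(nrow(primary))) {
    row <- primary[i, ]
    model <- config$profiles[[row$method]]
    # batches differ by seed stream and a small multiplicative depth jitter
    depth <- config$molecules_per_ng * row$input_ng *
      ifelse(row$batch == 1L, 1, 0.9)
    sample_seed <- (config$seed * 1000L + i * 7L + row$batch * 101L) %% .Machine$integer.max
    sim <- simulate_library(pool, model, total_molecules = round(depth),
                            seed = sample_seed,
                            read_length = config$read_length)
    sims[[row$sample]] <- sim
    if (write_fastq_files)
      write_fastq(sim$reads, file.path(config$out_dir,
                                       paste0(row$sample, ".fastq")))
    cfg <- trim_config(layout = model$kit_layout, adapter3 = model$adapter3,
                       min_length = config$min_length)
    pp <- preprocess_reads(sim$reads, cfg)
    processed[[row$sample]] <- pp$reads
    tallies[[row$sample]] <- pp$tally
    assignments[[row$sample]] <- assign_reads(pp$reads$sequence, pool)
  }

  counts <- build_count_matrix(assignments, pool,
                               metadata = primary[, c("sample", "method",
                                                      "input_ng", "batch",
                                                      "replicate")])
  canonical <- counts$canonical

  # derived methods: directional UMI collapse and the 5% subsample control
  derived <- d[d$method %in% c("deduped", "fivepercent"), , drop = FALSE]
  nx <- d[d$method == "nextflex", , drop = FALSE]
  for (i in seq_len(nrow(derived))) {
    row <- derived[i, ]
    parent <- nx$sample[nx$input_ng == row$input_ng & nx$batch == row$batch &
                        nx$replicate == row$replicate][1]
    if (row$method == "deduped") {
      groups <- group_reads_by_reference(processed[[parent]]$read_id,
                                         assignments[[parent]]$parent_id)
      dc <- dedup_counts(groups)
      col <- stats::setNames(rep(0L, nrow(pool)), pool$id)
      col[names(dc)] <- dc
    } else {
      sub_seed <- (config$seed * 1000L + 555L + i) %% .Machine$integer.max
      sub <- subsample_reads(processed[[parent]],
                             fraction = config$fivepercent_fraction,
                             seed = sub_seed)
      a <- assign_reads(sub$sequence, pool)
      assignments[[row$sample]] <- a
      tab <- table(a$parent_id[a$is_canonical %in% TRUE])
      col <- stats::setNames(rep(0L, nrow(pool)), pool$id)
      col[names(tab)] <- as.integer(tab)
    }
    canonical <- cbind(canonical, col)
    colnames(canonical)[ncol(canonical)] <- row$sample
  }

  normalized <- normalize_counts(canonical)

  # metric suite over the normalized canonical counts
  by_method <- split(d$sample, d$method)
  acc <- accuracy_error(normalized)
  detection <- lapply(by_method, function(s)
    detect(normalized[, s, drop = FALSE], threshold = 10))
  inconsistency <- lapply(detection, detection_inconsistency)
  trip <- lapply(by_method, function(s)
    triplicate_error(normalized[, s, drop = FALSE]))
  method_means <- lapply(by_method, function(s)
    rowMeans(normalized[, s, drop = FALSE]))
  overlap <- topn_overlap(method_means, n = min(20, nrow(pool)))
  iso_norm <- if (nrow(counts$isomir))
    sweep(counts$isomir, 2, attr(normalized, "size_factors")[colnames(counts$isomir)], "/")
  else counts$isomir
  false_iso <- if (nrow(iso_norm)) false_isomirs(iso_norm) else list()

  feats <- sequence_features(pool$sequence)
  # nT is omitted: base counts sum to length, so including all four counts
  # with length would alias the design; the terminal-dinucleotide factors
  # add up to 30 treatment-coded levels, so they enter only when the pool
  # is large enough to estimate them
  factor_cols <- c("gc_content", "length", "fold_g", "nA", "nC", "nG",
                   "has_duplet", "has_quadruplet",
                   if (nrow(pool) >= 96) c("first2", "last2"))
  var_factors <- feats[, factor_cols]
  # a characteristic constant across the pool carries no variance to explain
  informative <- vapply(var_factors, function(x) length(unique(x)) > 1,
                        logical(1))
  var_factors <- var_factors[, informative, drop = FALSE]
  decomps <- lapply(by_method, function(s)
    percent_variance(rowMeans(acc[, s, drop = FALSE]), var_factors))
  method_var <- vapply(by_method, function(s)
    stats::var(as.vector(log2(normalized[, s, drop = FALSE] + 1))), numeric(1))
  weighted <- weighted_percent_variance(decomps, method_var)

  # write the report bundle + manifest
  wt <- function(x, file) {
    path <- file.path(config$out_dir, file)
    utils::write.table(x, path, sep = "\t", quote = FALSE, col.names = NA)
    path
  }
  files <- c(
    file.path(config$out_dir, "reference_pool.fasta"),
    wt(canonical, "counts_canonical.tsv"),
    wt(counts$isomir, "counts_isomir.tsv"),
    wt(round(normalized, 4), "normalized_counts.tsv"),
    wt(round(acc, 4), "accuracy_error.tsv"),
    wt(do.call(rbind, inconsistency), "detection_inconsistency.tsv"),
    wt(do.call(cbind, trip), "triplicate_error.tsv"),
    wt(do.call(cbind, lapply(decomps, `[[`, "percent")),
       "variance_percent.tsv"),
    wt(round(weighted, 4), "variance_weighted.tsv")
  )
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  utils::write.table(manifest, file.path(config$out_dir, "manifest.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)

  invisible(list(counts = counts, canonical = canonical,
                 normalized = normalized,
                 metrics = list(accuracy_error = acc, detection = detection,
                                inconsistency = inconsistency,
                                triplicate_error = trip, overlap = overlap,
                                false_isomirs = false_iso),
                 variance = list(decompositions = decomps,
                                 weighted = weighted,
                                 method_variance = method_var),
                 tallies = tallies, manifest = manifest, pool = pool))
}
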