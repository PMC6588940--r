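#' Construct a library-preparation bias model
#'
#' Collects every tunable source of technical bias the simulator applies:
#' adapter-ligation preferences at the 5' and 3' ends (log-weights per
#' terminal dinucleotide), a secondary-structure term acting on supplied
#' fold energies, per-base composition terms, GC-dependent PCR efficiency,
#' PCR duplication over a configurable cycle count, homopolymer stutter,
#' isomiR-generating artifact rates, per-base sequencing error, and the kit
#' adapter layout. With all coefficients zero and all rates zero, the model
#' is neutral and the simulated pool stays equimolar in expectation.
#'
#' The default PCR efficiency of 0.625 is the conservative per-cycle
#' duplication probability used for starting-molecule estimation; real
#' miRNA PCR efficiencies usually run higher (0.75-0.95).
#'
#' @param kit_layout One of `"nextflex"` (ligated degenerate adapters, 4+4
#'   UMI), `"clontech"` (template-switch + poly-A, no UMI), `"plain"`
#'   (ligated fixed adapters, no UMI).
#' @param lig5_weights,lig3_weights Named numeric log-weights keyed by the
#'   first/last dinucleotide of the insert (missing keys count as 0).
#' @param struct_coeff Coefficient per kcal/mol on the fold energy.
#' @param base_count_coeffs Named numeric, per-occurrence log-weight per
#'   base (names among A/C/G/T).
#' @param rt_struct_coeff Reverse-transcription structure coefficient
#'   (applied with the ligation terms for template-switch chemistry).
#' @param pcr_efficiency_base Per-cycle duplication probability in (0, 1].
#' @param pcr_efficiency_gc_coeff Linear GC adjustment: efficiency of a
#'   molecule with GC fraction g is `base + coeff * (g - 0.5)`, clamped
#'   to (0, 1].
#' @param pcr_cycles Number of PCR cycles.
#' @param stutter_prob Per-copy probability that a homopolymer run of
#'   length >= 4 contracts or expands by one base.
#' @param artifact_rates Named numeric with entries `trim3`, `ext3`,
#'   `strand_invasion5`, `concatamer5`, each in \[0, 1\]. The 5' mechanisms
#'   are template-switch artifacts and only act under the clontech layout.
#' @param seq_error_rate Per-base substitution probability.
#' @param adapter3 3' adapter sequence used in read construction.
#' @param umi_len Degenerate bases per adapter end; forced to 4 for
#'   nextflex and 0 otherwise.
#' @return A `bias_model` list.
#' @examples
#' neutral <- bias_model(pcr_cycles = 0, seq_error_rate = 0)
#' @export
bias_model <- function(kit_layout = c("nextflex", "clontech", "plain"),
                       lig5_weights = numeric(0),
                       lig3_weights = numeric(0),
                       struct_coeff = 0,
                       base_count_coeffs = numeric(0),
                       rt_struct_coeff = 0,
                       pcr_efficiency_base = 0.625,
                       pcr_efficiency_gc_coeff = 0,
                       pcr_cycles = 18,
                       stutter_prob = 0,
                       artifact_rates = c(trim3 = 0, ext3 = 0,
                                          strand_invasion5 = 0,
                                          concatamer5 = 0),
                       seq_error_rate = 0,
                       adapter3 = "TGGAATTCTCGGGTGCCAAGG",
                       umi_len = NULL) {
  kit_layout <- match.arg(kit_layout)
  rates <- c(trim3 = 0, ext3 = 0, strand_invasion5 = 0, concatamer5 = 0)
  rates[names(artifact_rates)] <- artifact_rates
  if (any(rates < 0 | rates > 1)) stop("artifact rates must be in [0, 1]")
  if (stutter_prob < 0 || stutter_prob > 1) stop("stutter_prob must be in [0, 1]")
  if (seq_error_rate < 0 || seq_error_rate > 1) stop("seq_error_rate must be in [0, 1]")
  if (pcr_efficiency_base <= 0 || pcr_efficiency_base > 1)
    stop("pcr_efficiency_base must be in (0, 1]")
  # the GC adjustment spans at most +/- 0.5 * |coeff|
  if (pcr_efficiency_base + 0.5 * abs(pcr_efficiency_gc_coeff) > 1 ||
      pcr_efficiency_base - 0.5 * abs(pcr_efficiency_gc_coeff) <= 0)
    stop("pcr_efficiency_base plus the maximum GC adjustment must stay in (0, 1]")
  if (pcr_cycles < 0 || pcr_cycles != round(pcr_cycles))
    stop("pcr_cycles must be a nonnegative integer")
  if (!is.null(umi_len) && kit_layout == "nextflex" && umi_len != 4)
    stop("nextflex layout uses a fixed 4+4 UMI design")

  model <- list(
    kit_layout = kit_layout,
    lig5_weights = lig5_weights,
    lig3_weights = lig3_weights,
    struct_coeff = struct_coeff,
    base_count_coeffs = base_count_coeffs,
    rt_struct_coeff = rt_struct_coeff,
    pcr_efficiency_base = pcr_efficiency_base,
    pcr_efficiency_gc_coeff = pcr_efficiency_gc_coeff,
    pcr_cycles = as.integer(pcr_cycles),
    stutter_prob = stutter_prob,
    artifact_rates = rates,
    seq_error_rate = seq_error_rate,
    adapter3 = adapter3,
    # UMI tagging is a property of the chemistry: degenerate adapter bases
    # exist only in the nextflex-style layout
    umi_len = if (kit_layout == "nextflex") 4L else 0L
  )
  class(model) <- "bias_model"
  model
}

# per-molecule PCR duplication probability under the GC-linear model
pcr_efficiency <- function(model, gc) {
  pmin(1, pmax(1e-12,
    model$pcr_efficiency_base + model$pcr_efficiency_gc_coeff * (gc - 0.5)))
}

#' Sequence-dependent selection weights for library preparation
#'
#' Computes the relative probability that each pool sequence survives
#' adapter ligation / reverse transcription, as a log-linear model over
#' terminal dinucleotides, fold energy, and base composition:
#' `w_i = exp(lig5[first2_i] + lig3[last2_i] + struct_coeff * FoldG_i +
#' sum_b coeff_b * n_b(i))`. With all coefficients zero every weight is 1.
#'
#' @param pool A `reference_pool`.
#' @param model A `bias_model`.
#' @param fold_energies Named numeric (kcal/mol) covering every pool id, or
#'   `NULL` to use the maximum-base-pairing proxy (see
#'   [fold_energy_proxy()]); only consulted when a structure coefficient is
#'   nonzero.
#' @return Named positive numeric vector of weights, one per pool id.
#' @examples
#' pool <- build_reference_pool(n = 5, seed = 1)
#' selection_weights(pool, bias_model()) # all 1
#' @export
selection_weights <- function(pool, model, fold_energies = NULL) {
  validate_reference_pool(pool)
  struct <- model$struct_coeff + model$rt_struct_coeff
  if (struct != 0) {
    if (is.null(fold_energies)) {
      fold_energies <- fold_energy_proxy(pool$sequence)
      names(fold_energies) <- pool$id
    }
    missing <- setdiff(pool$id, names(fold_energies))
    if (length(missing) > 0)
      stop("fold energies missing for ids: ", paste(missing, collapse = ", "))
    fe <- fold_energies[pool$id]
  } else {
    fe <- rep(0, nrow(pool))
  }

  lw <- function(weights, keys) {
    out <- rep(0, length(keys))
    hit <- keys %in% names(weights)
    out[hit] <- weights[keys[hit]]
    out
  }
  first2 <- substr(pool$sequence, 1, 2)
  last2 <- substr(pool$sequence, nchar(pool$sequence) - 1, nchar(pool$sequence))
  log_w <- lw(model$lig5_weights, first2) + lw(model$lig3_weights, last2) +
    struct * fe
  for (b in names(model$base_count_coeffs)) {
    nb <- nchar(pool$sequence) - nchar(gsub(b, "", pool$sequence, fixed = TRUE))
    log_w <- log_w + model$base_count_coeffs[[b]] * nb
  }
  w <- exp(log_w)
  if (any(!is.finite(w)) || any(w <= 0))
    stop("selection weights must be finite and positive; check coefficients")
  names(w) <- pool$id
  w
}

#' Maximum-base-pairing proxy for RNA fold energy
#'
#' A Nussinov-style dynamic program maximising Watson-Crick plus G:U wobble
#' pairs with a minimum hairpin loop of 3 nt, scored at -1.0 per pair.
#' This is a structure-capacity proxy, not a thermodynamic minimum free
#' energy; supply real fold energies (e.g. computed externally with an RNA
#' folding tool) whenever available. Results are flagged with
#' `attr(, "proxy") = TRUE`.
#'
#' @param sequences Character vector of A/C/G/T(/U) sequences.
#' @param min_loop Minimum unpaired loop length (default 3).
#' @return Numeric vector of proxy energies (kcal/mol-like, <= 0), with
#'   attribute `proxy = TRUE`.
#' @export
fold_energy_proxy <- function(sequences, min_loop = 3L) {
  can_pair <- function(a, b) {
    (a == "A" && b == "T") || (a == "T" && b == "A") ||
      (a == "G" && b == "C") || (a == "C" && b == "G") ||
      (a == "G" && b == "T") || (a == "T" && b == "G")
  }
  one <- function(seq) {
    s <- strsplit(chartr("U", "T", seq), "")[[1]]
    n <- length(s)
    if (n < min_loop + 2) return(0)
    dp <- matrix(0L, n, n)
    for (len in (min_loop + 2):n) {
      for (i in 1:(n - len + 1)) {
        j <- i + len - 1
        best <- dp[i + 1, j]
        for (k in (i + min_loop + 1):j) {
          if (can_pair(s[i], s[k])) {
            left <- if (k > i + 1) dp[i + 1, k - 1] else 0L
            right <- if (k < j) dp[k + 1, j] else 0L
            best <- max(best, 1L + left + right)
          }
        }
        dp[i, j] <- best
      }
    }
    -1.0 * dp[1, n]
  }
  out <- vapply(sequences, one, numeric(1), USE.NAMES = FALSE)
  attr(out, "proxy") <- TRUE
  out
}
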