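---
title: "Dissecting technical bias in small RNA sequencing with srnabench"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Dissecting technical bias in small RNA sequencing with srnabench}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(srnabench)
```

## The problem

Small RNA sequencing quantifies mature miRNAs (~16-30 nt) by ligating
adapters to each molecule, reverse transcribing, PCR-amplifying and
sequencing. Every one of those steps is sequence-dependent: adapter
ligases prefer certain insert ends, secondary structure impedes ligation
and reverse transcription, and PCR favours particular GC compositions.
The practical consequence is that two library-preparation chemistries can
report abundances for the same sample that differ by orders of magnitude
per miRNA, and that sequence variants (isomiRs) can be *created* by the
protocol rather than by biology.

Commercial chemistries attack this differently: fixed ligated adapters
(the common baseline), degenerate-base adapters whose 4+4 random
nucleotides both soften ligation bias and act as an 8-nt unique molecular
identifier (UMI, `4^8 = 65,536` labels), and ligation-free
template-switch/poly-A chemistries. `srnabench` provides (i) a simulator
that generates reads from an equimolar synthetic pool under explicit,
configurable models of each bias source with complete ground truth, and
(ii) the full downstream measurement suite — trimming, isomiR-aware
quantification, directional UMI deduplication, median-of-ratios
normalization, and the accuracy/detection/consistency metrics — so the
standard claims about bias mitigation can be exercised, end to end, on
data whose truth is known.

## The simulator

A **reference pool** is a set of unique 16-30 nt sequences with molar
fractions (equimolar by default; the default size of 962 mirrors the
widely used commercial universal reference pool). The simulation pipeline
is:

1. **Selection weights** (`selection_weights()`): library-preparation
   survival is log-linear in sequence characteristics,
   `w_i = exp(lig5[first2_i] + lig3[last2_i] + beta_s * FoldG_i +
   sum_b beta_b n_b(i))`. With all coefficients zero every weight is 1
   and the pool stays equimolar in expectation.
2. **Molecule sampling** (`sample_molecules()`): a multinomial draw over
   `molar_fraction * weight`. For the degenerate-adapter layout each
   molecule receives an 8-nt UMI *here*, before reverse transcription and
   PCR — that is what the chemistry does, and it is what makes UMI
   deduplication a valid estimator of pre-amplification molecules. PCR
   copies inherit the UMI exactly; UMI errors arise only from sequencing
   error.
3. **Artifact injection** (`inject_isomir_artifacts()`): independent
   per-molecule events — 3' trimming (1-2 nt), 3' non-templated A/T
   addition (1-2 nt), and, only for the template-switch layout, 5'
   truncation by strand invasion (1-3 nt) and 5' extension by
   template-switch-oligo concatamers (1-3 nt). Artifacts are injected
   before amplification, where the chemistry places them, and every event
   is recorded in a ledger.
4. **Amplification** (`amplify()`): per cycle, each copy duplicates with
   probability `e_i = e0 + beta_gc (GC_i - 0.5)` clamped to (0, 1], so
   the expected family size is `(1+e_i)^c`. The default `e0 = 0.625` is
   the conservative per-cycle efficiency also used by the
   starting-molecule estimator. PCR stutter contracts or expands the
   first homopolymer run of length >= 4 by one base with a per-copy
   probability. Internally identical copies are tracked as per-lineage
   counts; this is distributionally identical to simulating each copy
   event (copies within a lineage are exchangeable, and stuttered copies
   branch into their own lineage), and keeps 6,000-fold families
   tractable.
5. **Sequencing** (`sequence_reads()`): one single-end read per copy,
   assembled per layout — `[UMI4][insert][UMI4][adapter...]` for
   degenerate adapters, `[GGG][insert][polyA...]` for template-switch,
   `[insert][adapter...]` for plain — truncated/padded to the 51-nt
   machine read length, with independent per-base substitution errors
   applied to the entire read (UMI bases included) and constant Q40
   qualities (qualities are never used analytically).

Identical configuration and seed give byte-identical FASTQ and truth
tables.

### What the generator does and does not emulate

It reproduces the *mechanisms* of bias (terminal-dinucleotide ligation
preference, structure- and composition-coupled selection, GC-dependent
amplification, UMI saturation, artifact-generated isomiRs, read-through
into adapters) at magnitudes chosen to be realistic in order of
magnitude. No public measurement pins down per-dinucleotide ligation
log-weights, so the shipped kit profiles (`method_profiles()`) are
illustrative, in \[-1, 1\], not fitted; conclusions from the test-bed are
therefore about directions and mechanisms, not about reproducing any
laboratory's exact numbers. Not modelled at all: indel sequencing errors,
quality-score variation, paired-end reads, and biological RNA classes
beyond an optional labeled reference (`classify_rna_classes()` covers the
read-classification logic itself).

## Preprocessing and quantification

Trimming is exact-match and kit-aware (`preprocess_reads()`): the 3'
adapter rule removes the leftmost occurrence of a full internal adapter
or of an adapter prefix of >= 5 nt running to the read end — exact
matching keeps the stage deterministic; error-tolerant matching is
deliberately out of scope. The degenerate-adapter layout then takes
first-4 + last-4 bases as the UMI (appended to the read id as
`id_UMI`), removing reads with any unknown base in the UMI. The
template-switch layout drops three 5' bases and truncates at the first
run of >= 10 adenines — applied literally, so genuine A-runs inside an
insert truncate too; this known failure mode is one reason that chemistry
cannot distinguish isomiRs ending in adenines. The length filter keeps
inserts >= 16 nt in synthetic-pool mode (the shortest pool sequence);
18 nt is the appropriate floor for biological libraries.

Assignment (`assign_read()`) is an explicit, configurable policy rather
than an opaque aligner: exact canonical match, else the reference
minimizing `|5' offset| + 3' offset + internal mismatches + 3'
non-templated additions` within bounds (defaults 4/4/2/3), ties broken by
cost then lexicographic id. isomiRs are keyed by their full insert
sequence. A brute-force enumeration oracle checks the policy search
property-style in the tests.

## Directional UMI deduplication

Reads are grouped per assigned reference (so isomiRs sharing a parent and
a UMI count as duplicates of it), then UMIs are clustered with the
directional rule: an edge runs from UMI `a` to `b` when they differ at
one position and `count(a) >= 2*count(b) - 1`; clusters grow by BFS from
count-sorted seeds. The cluster count is the deduplicated quantity. Two
numerical consequences worth knowing: (i) the rule absorbs UMIs that look
like sequencing errors of an abundant UMI, which is exactly right after
amplification, but at *zero* amplification equal singleton counts satisfy
`1 >= 2*1 - 1`, so two genuinely distinct molecules with adjacent UMIs
would merge — negligible whenever per-reference molecules are sparse in
the 65,536-label space; (ii) with `m` molecules and `U` labels the
expected distinct-UMI count is `U(1 - (1 - 1/U)^m)`, so collision loss is
about `m^2/2U` and stays under 1% up to roughly 1,300
molecules/reference; `estimate_starting_molecules()` flags estimates
above 20% of the label space as saturating.

## Normalization and metrics

Size factors are median-of-ratios: per-sample median (taken on the log
scale, the standard convention) of count-to-geometric-mean ratios over
features with all-positive counts. All thresholds follow strict
inequalities: detection uses `> 10` normalized reads (miRNA) and `> 100`
(isomiR) in all replicates; the similarity filter is `> 1` in all
samples. Detection inconsistency is `(U_X - U_123)/U_X * 100`. Accuracy
error on the equimolar pool is `log2(|x_i - mean(x)| + 1)`; batch and
triplicate errors apply the same transform to deviations from batch/
replicate means. The `+1` pseudocount is a deliberate choice: the bare
log2 of an absolute difference is undefined at zero, and `+1` maps
perfect agreement to exactly 0 while preserving monotonicity in the
deviation. In an equimolar synthetic pool every isomiR above threshold is
false by construction; `false_isomirs()` reports the total, the
per-parent counts, and the expressions.

## Variance decomposition

`percent_variance()` attributes response variance to sequence
characteristics (GC, length, fold energy, terminal dinucleotides, base
counts, duplet/quadruplet flags) via type-II sums of squares computed by
explicit least-squares refits: `SS_f = RSS(model without f) - RSS(full)`,
reported as a percent of total SS. Treatment coding with lexicographic
first level is used throughout (the coding convention is otherwise
arbitrary and does not affect type-II SS). In orthogonal designs the
shares plus the residual sum to 100 and equal sequential shares; in
non-orthogonal designs negative components are floored at zero with a
warning. Since base counts sum to sequence length, `nT` must be dropped
whenever `length` and the other three counts are in the model, and the
16-level dinucleotide factors need on the order of a hundred observations
— `run_pipeline()` enforces both. The variance-weighted view multiplies
each method's shares by `var(method)/max(var)`, so equal raw shares rank
methods by how much absolute variance a characteristic drives; the exact
weighting formula is our interpretation, adopted because it preserves
that ordering property. Fold energies can be supplied per id; otherwise a
Nussinov-style maximum-base-pairing proxy (-1 per pair, minimum loop 3,
G:U wobble allowed) is used and flagged — it ranks structure capacity,
and is not a thermodynamic minimum free energy.

## The pipeline and the problem sizes used

`run_pipeline()` simulates each design sample under its kit profile,
derives the UMI-collapsed and 5%-subsample methods from their
degenerate-adapter parents (derived labels validate only when such a
parent exists), quantifies, normalizes all samples jointly, and writes
the metric and variance tables with an md5 manifest; reruns are
byte-identical. Batches are emulated as distinct seed streams plus a 0.9x
depth jitter. The bundled demo runs 6 methods x 3 replicates on a
120-sequence pool at a few thousand molecules per sample with 2-4 PCR
cycles — sizes chosen so the whole test suite, including 20-seed
direction checks (UMI collapse reduces accuracy error and count variance
under GC-biased PCR; the template-switch artifact profile produces more
false isomiRs per parent than the degenerate-adapter profile; triplicate
error rises with expression), completes in about a minute. The same code
paths scale to the 962-sequence pool at ~100x coverage, used by the
acceptance script.

## Known limitations

Exact-match trimming misses adapters containing sequencing errors (such
reads usually end up unassigned); the assignment policy is a declared
stand-in for aligner-based isomiR calling, not a reimplementation of any
specific tool; ligation-bias magnitudes are illustrative; the stutter
model touches only the first homopolymer run; and no statistical testing
machinery (effect sizes, F/t/p values on real libraries) is included —
the package measures directions and magnitudes on data with known truth.
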