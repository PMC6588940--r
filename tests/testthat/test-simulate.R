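test_that("molecule sampling is multinomial over weighted fractions", {
  pool <- build_reference_pool(n = 100, seed = 5)
  w <- selection_weights(pool, bias_model())

  # a single molecule gets a single 8-mer UMI
  sm1 <- sample_molecules(pool, w, total_molecules = 1,
                          umi_length_each_end = 4, seed = 1)
  expect_equal(nrow(sm1$molecules), 1)
  expect_equal(nchar(sm1$molecules$umi), 8)
  expect_equal(sum(sm1$truth$per_reference$true_molecules_pre_pcr), 1)

  # equimolar neutral sampling: every count within 5 SD of N/n
  N <- 1e6
  sm <- sample_molecules(pool, w, total_molecules = N,
                         umi_length_each_end = 0, seed = 2)
  counts <- sm$truth$per_reference$true_molecules_pre_pcr
  expect_equal(sum(counts), N)
  sd_bin <- sqrt(N * (1 / 100) * (1 - 1 / 100))
  expect_true(all(abs(counts - N / 100) < 5 * sd_bin))
})

test_that("neutral-model counts pass a chi-square equimolarity check", {
  pool <- build_reference_pool(n = 100, seed = 5)
  w <- selection_weights(pool, bias_model())
  pvals <- vapply(1:5, function(s) {
    sm <- sample_molecules(pool, w, 1e6, umi_length_each_end = 0, seed = s)
    suppressWarnings(stats::chisq.test(
      sm$truth$per_reference$true_molecules_pre_pcr)$p.value)
  }, numeric(1))
  expect_gt(mean(pvals), 0.001)
})

test_that("amplification matches the (1+e)^c closed form", {
  pool <- toy_pool(n = 1)
  w <- selection_weights(pool, bias_model())
  model <- bias_model(pcr_efficiency_base = 0.625, pcr_cycles = 18)

  # zero cycles is the identity
  sm <- sample_molecules(pool, w, 50, umi_length_each_end = 4, seed = 1)
  m0 <- bias_model(pcr_cycles = 0)
  expect_identical(amplify(sm$molecules, m0, seed = 2), sm$molecules)

  # 200 molecules, 10 seeds: mean family size within 10% of 1.625^18
  means <- vapply(1:10, function(s) {
    sm <- sample_molecules(pool, w, 200, umi_length_each_end = 4, seed = s)
    amp <- amplify(sm$molecules, model, seed = s + 100)
    sum(amp$count) / 200
  }, numeric(1))
  expect_equal(mean(means), 1.625^18, tolerance = 0.1)
})

test_that("stutter only mutates homopolymer runs and is off by default", {
  mol <- data.frame(molecule_id = c("m1", "m2"),
                    parent_id = c("p1", "p2"),
                    sequence = c("ACGTACGTACGTACGT", "ACGTAAAAACGTACGT"),
                    umi = c("AAAACCCC", "GGGGTTTT"),
                    is_artifact = FALSE, artifact_kind = "",
                    count = 1L, stringsAsFactors = FALSE)
  m_off <- bias_model(pcr_cycles = 5, stutter_prob = 0)
  amp <- amplify(mol, m_off, seed = 3)
  expect_setequal(unique(amp$sequence), mol$sequence)

  m_on <- bias_model(pcr_cycles = 8, stutter_prob = 0.2)
  amp2 <- amplify(mol, m_on, seed = 4)
  # the run-free molecule never stutters
  s1 <- amp2$sequence[amp2$molecule_id == "m1"]
  expect_setequal(unique(s1), mol$sequence[1])
  # the A5 run contracts/expands by single bases
  s2 <- unique(amp2$sequence[amp2$molecule_id == "m2"])
  expect_true(length(s2) > 1)
  expect_true(all(grepl("^ACGTA+CGTACGT$", s2)))
  expect_true(all(amp2$artifact_kind[amp2$sequence != mol$sequence[2] &
                                     amp2$molecule_id == "m2"] != ""))
})

test_that("artifact injection rates and layout gating are honoured", {
  pool <- build_reference_pool(n = 10, seed = 6)
  w <- selection_weights(pool, bias_model())
  sm <- sample_molecules(pool, w, 1e5, umi_length_each_end = 0, seed = 1)

  # all rates zero: empty ledger, sequences untouched
  clean <- inject_isomir_artifacts(sm$molecules, bias_model(), seed = 2)
  expect_equal(nrow(attr(clean, "artifact_ledger")), 0)
  expect_identical(clean$sequence, sm$molecules$sequence)

  # binomial count of 3' trims at rate 0.1 over 1e5 molecules
  m <- bias_model(artifact_rates = c(trim3 = 0.1))
  art <- inject_isomir_artifacts(sm$molecules, m, seed = 3)
  n_art <- sum(attr(art, "artifact_ledger")$count)
  expect_lt(abs(n_art - 1e4), 5 * sqrt(1e5 * 0.1 * 0.9))

  # 5' strand invasion is a template-switch artifact: gated off outside
  # the clontech layout even when its rate is positive
  m_nx <- bias_model("nextflex",
                     artifact_rates = c(strand_invasion5 = 0.5,
                                        concatamer5 = 0.5))
  gated <- inject_isomir_artifacts(sm$molecules, m_nx, seed = 4)
  expect_equal(nrow(attr(gated, "artifact_ledger")), 0)

  m_cl <- bias_model("clontech",
                     artifact_rates = c(strand_invasion5 = 0.2))
  hit <- inject_isomir_artifacts(sm$molecules[1:1000, ], m_cl, seed = 5)
  ledger <- attr(hit, "artifact_ledger")
  expect_true(all(ledger$kind == "strand_invasion5"))
  expect_gt(sum(ledger$count), 0)
  expect_true(all(ledger$count <= 1000))
})

test_that("reads are constructed per layout at the machine read length", {
  mol <- data.frame(molecule_id = "m1", parent_id = "p1",
                    sequence = "ACGTACGTACGTACGTACGT",
                    umi = "AAAATTTT", is_artifact = FALSE,
                    artifact_kind = "", count = 1L,
                    stringsAsFactors = FALSE)
  m <- bias_model("nextflex", seq_error_rate = 0)
  sr <- sequence_reads(mol, m, read_length = 51, seed = 1)
  read <- sr$reads$sequence
  expect_equal(nchar(read), 51)
  expect_equal(substr(read, 1, 8), "AAAAACGT")
  expect_equal(substr(read, 25, 28), "TTTT")
  expect_equal(substr(read, 29, 29 + nchar(m$adapter3) - 1), m$adapter3)
  expect_equal(sr$reads$quality, strrep("I", 51))

  # clontech: template-switch bases then insert then a poly-A run
  m_cl <- bias_model("clontech", seq_error_rate = 0)
  mol_cl <- mol; mol_cl$umi <- ""
  r_cl <- sequence_reads(mol_cl, m_cl, read_length = 51, seed = 1)$reads$sequence
  expect_equal(substr(r_cl, 4, 23), mol$sequence)
  expect_match(substr(r_cl, 24, 51), "^A+$")

  # plain: insert then adapter
  m_pl <- bias_model("plain", seq_error_rate = 0)
  r_pl <- sequence_reads(mol_cl, m_pl, read_length = 51, seed = 1)$reads$sequence
  expect_equal(substr(r_pl, 1, 20), mol$sequence)
  expect_equal(substr(r_pl, 21, 21 + nchar(m$adapter3) - 1), m$adapter3)
})

test_that("sequencing error counts are binomial at the configured rate", {
  pool <- build_reference_pool(n = 20, seed = 8)
  model0 <- bias_model(pcr_cycles = 0, seq_error_rate = 0)
  model1 <- bias_model(pcr_cycles = 0, seq_error_rate = 0.01)
  sim0 <- simulate_library(pool, model0, total_molecules = 2000, seed = 9)
  sim1 <- simulate_library(pool, model1, total_molecules = 2000, seed = 9)
  # same seed, same molecules: reads differ only by injected errors
  expect_identical(sim0$truth$reads$umi, sim1$truth$reads$umi)
  mism <- sum(mapply(function(a, b) sum(utf8ToInt(a) != utf8ToInt(b)),
                     sim0$reads$sequence, sim1$reads$sequence))
  bases <- 51 * nrow(sim1$reads)
  expect_lt(abs(mism - bases * 0.01), 5 * sqrt(bases * 0.01 * 0.99))
})

test_that("identical configuration and seed give byte-identical output", {
  pool <- build_reference_pool(n = 15, seed = 10)
  model <- bias_model(pcr_cycles = 3, seq_error_rate = 0.005,
                      artifact_rates = c(trim3 = 0.05))
  a <- simulate_library(pool, model, 800, seed = 123)
  b <- simulate_library(pool, model, 800, seed = 123)
  expect_identical(a$reads, b$reads)
  expect_identical(a$truth$reads, b$truth$reads)
  fa <- tempfile(fileext = ".fastq"); fb <- tempfile(fileext = ".fastq")
  write_fastq(a$reads, fa); write_fastq(b$reads, fb)
  expect_identical(unname(tools::md5sum(fa)), unname(tools::md5sum(fb)))
})

test_that("distinct UMIs per reference follow the occupancy closed form", {
  pool <- toy_pool(n = 1)
  w <- selection_weights(pool, bias_model())
  U <- umi_space_size(4)
  m <- 1000
  expected <- U * (1 - (1 - 1 / U)^m)
  # variance of the number of occupied labels
  v <- U * (1 - 1 / U)^m + U * (U - 1) * (1 - 2 / U)^m -
    U^2 * (1 - 1 / U)^(2 * m)
  sm <- sample_molecules(pool, w, m, umi_length_each_end = 4, seed = 31)
  observed <- length(unique(sm$molecules$umi))
  expect_equal(expected, 992.4, tolerance = 1e-3)
  expect_lt(abs(observed - expected), 3 * sqrt(v) + 1)
})
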