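test_that("assignment handles exact, isomiR and unassignable inserts", {
  pool <- toy_pool(n = 8, seed = 42)
  # exact canonical match
  a <- assign_read(pool$sequence[3], pool)
  expect_equal(a$parent_id, pool$id[3])
  expect_true(a$is_canonical)
  expect_equal(a$cost, 0L)

  # one trimmed 3' base: isomiR of the same reference, cost 1
  s <- pool$sequence[3]
  trimmed <- substr(s, 1, nchar(s) - 1)
  a2 <- assign_read(trimmed, pool)
  expect_equal(a2$parent_id, pool$id[3])
  expect_false(a2$is_canonical)
  expect_equal(a2$cost, 1)

  # a read unrelated to every reference is unassigned
  a3 <- assign_read(strrep("AC", 12), pool)
  expect_true(is.na(a3$parent_id))
})

test_that("assignment agrees with the brute-force enumeration oracle", {
  set.seed(77)
  for (rep in 1:5) {
    pool <- build_reference_pool(n = sample(5:20, 1), seed = rep)
    # reads: mutated references (end offsets, mismatches, additions) and noise
    reads <- character(100)
    for (i in seq_len(100)) {
      s <- sample(pool$sequence, 1)
      o5 <- sample(0:5, 1); o3 <- sample(0:5, 1)
      s <- substr(s, 1 + o5, nchar(s) - o3)
      if (runif(1) < 0.5 && nchar(s) > 2) {
        p <- sample(nchar(s), 1)
        substr(s, p, p) <- sample(c("A", "C", "G", "T"), 1)
      }
      if (runif(1) < 0.4)
        s <- paste0(s, paste(sample(c("A", "T"), sample(1:4, 1),
                                    replace = TRUE), collapse = ""))
      if (runif(1) < 0.1)
        s <- paste(sample(c("A", "C", "G", "T"), 20, replace = TRUE),
                   collapse = "")
      reads[i] <- s
    }
    got <- assign_reads(reads, pool)
    for (i in seq_len(100)) {
      want <- oracle_assign(reads[i], pool)
      expect_identical(got$parent_id[i], want$parent_id)
      if (!is.na(want$parent_id))
        expect_equal(got$cost[i], want$cost)
    }
  }
})

test_that("bias-free error-free simulation recovers truth counts exactly", {
  pool <- build_reference_pool(n = 50, seed = 14)
  model <- bias_model(pcr_cycles = 0, seq_error_rate = 0)
  sim <- simulate_library(pool, model, 5000, seed = 15)
  pp <- preprocess_reads(sim$reads, trim_config("nextflex"))
  a <- assign_reads(pp$reads$sequence, pool)
  cm <- build_count_matrix(list(s1 = a), pool)
  expect_equal(nrow(cm$isomir), 0)
  truth <- sim$truth$per_reference
  expect_equal(unname(cm$canonical[truth$id, "s1"]),
               truth$true_molecules_pre_pcr)
})

test_that("injected 3' trim artifacts are recovered as isomiRs at rate r", {
  # references of >= 19 nt so a 1-2 nt trim never falls under the length
  # filter and every artifact read survives to assignment
  pool <- build_reference_pool(n = 40, length_range = c(19, 28), seed = 16)
  r <- 0.05
  model <- bias_model(pcr_cycles = 0, seq_error_rate = 0,
                      artifact_rates = c(trim3 = r))
  sim <- simulate_library(pool, model, 20000, seed = 17)
  pp <- preprocess_reads(sim$reads, trim_config("nextflex"))
  expect_equal(nrow(pp$reads), 20000)
  a <- assign_reads(pp$reads$sequence, pool)
  iso_frac <- mean(!a$is_canonical & !is.na(a$parent_id))
  expect_lt(abs(iso_frac - r), 3 * sqrt(r * (1 - r) / 20000))
})

test_that("count matrices tabulate per-sample assignments", {
  pool <- toy_pool(n = 4, seed = 50)
  a <- data.frame(insert = rep(pool$sequence[1], 3),
                  parent_id = rep(pool$id[1], 3),
                  is_canonical = TRUE, cost = 0,
                  stringsAsFactors = FALSE)
  cm <- build_count_matrix(list(S = a), pool)
  expect_equal(unname(cm$canonical[pool$id[1], "S"]), 3L)
  expect_equal(sum(cm$canonical), 3)

  # one artifact read becomes exactly one isomiR row
  iso_seq <- substr(pool$sequence[2], 1, nchar(pool$sequence[2]) - 1)
  a2 <- rbind(a, data.frame(insert = iso_seq, parent_id = pool$id[2],
                            is_canonical = FALSE, cost = 1))
  cm2 <- build_count_matrix(list(S = a2), pool)
  expect_equal(nrow(cm2$isomir), 1)
  expect_equal(rownames(cm2$isomir), paste(pool$id[2], iso_seq, sep = "|"))

  expect_error(build_count_matrix(stats::setNames(list(a, a), c("S", "S")),
                                  pool), "duplicate")
})

test_that("RNA-class classification uses seed-prefix matching with
           miRNA-priority deduplication", {
  ref <- data.frame(
    class = c("miRNA", "piRNA", "piRNA", "rRNA"),
    id = c("mir1", "pir1", "pir2", "rrna1"),
    sequence = c("ACGTACGTACGTACGTACGTACGTACGTACGT",
                 "ACGTACGTACGTACGTACGTACGTACGTACGT",  # identical to mir1
                 "TTTTCCCCGGGGAAAATTTTCCCCGGGGAAAA",
                 "GGGGGGGGGGCCCCCCCCCCGGGGGGGGGGCC"),
    stringsAsFactors = FALSE)
  reads <- c("ACGTACGTACGTACGTACGTACGTACGTACGT",  # = miRNA entry
             "TTTTCCCCGGGGAAAATTTT",              # prefix of pir2
             "ACACACACACACACACACAC")              # matches nothing
  out <- classify_rna_classes(reads, ref)
  # the duplicated piRNA entry was removed from the piRNA reference
  expect_false("pir1" %in% out$reference$id)
  expect_equal(unname(out$counts["miRNA"]), 1L)
  expect_equal(unname(out$counts["piRNA"]), 1L)
  expect_equal(unname(out$counts["Undetermined"]), 1L)
  expect_error(classify_rna_classes(reads, ref[0, ]), "empty")
})
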