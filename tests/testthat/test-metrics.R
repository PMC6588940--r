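test_that("median-of-ratios size factors match their closed forms", {
  a <- c(10, 50, 200, 7, 33)
  # identical samples: unit factors
  expect_equal(unname(size_factors(cbind(s1 = a, s2 = a))), c(1, 1))
  # doubling one sample splits the factors as (1/sqrt(2), sqrt(2))
  expect_equal(unname(size_factors(cbind(s1 = a, s2 = 2 * a))),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  # a feature with a zero is excluded from the reference set
  withzero <- rbind(cbind(s1 = a, s2 = 2 * a), c(0, 100))
  expect_equal(unname(size_factors(withzero)),
               c(1 / sqrt(2), sqrt(2)), tolerance = 1e-12)
  expect_error(size_factors(cbind(c(0, 1), c(1, 0))), "all-positive")
})

test_that("size factors agree with the DESeq2 estimator", {
  skip_if_not_installed("DESeq2")
  set.seed(7)
  m <- matrix(rpois(500, lambda = 60) + 1L, ncol = 5,
              dimnames = list(NULL, paste0("s", 1:5)))
  m[, 3] <- m[, 3] * 3L
  expect_equal(unname(size_factors(m)),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-10)
})

test_that("scaling one sample scales its relative factor by k", {
  # size factors are defined up to a common scale: multiplying sample 2 by
  # k multiplies sf2/sf1 by k, and the normalized matrix changes only by a
  # common constant (the scaled sample shifts every geometric mean)
  set.seed(8)
  m <- matrix(rpois(300, 50) + 1, ncol = 3)
  f0 <- size_factors(m)
  m2 <- m; m2[, 2] <- m2[, 2] * 4
  f1 <- size_factors(m2)
  expect_equal((f1[2] / f1[1]) / (f0[2] / f0[1]), 4, tolerance = 1e-9)
  n0 <- normalize_counts(m); n1 <- normalize_counts(m2)
  ratio <- n1 / n0
  expect_lt(diff(range(ratio)), 1e-9)
})

test_that("accuracy error is the log2 absolute deviation from the mean", {
  expect_equal(accuracy_error(c(120, 80, 100, 100)),
               c(log2(21), log2(21), 0, 0))
  expect_equal(accuracy_error(rep(42, 10)), rep(0, 10))
  expect_error(accuracy_error(5), ">= 2 features")
  # monotone in |difference| and zero only at equality
  errs <- accuracy_error(c(100, 101, 110, 200))
  expect_true(all(errs >= 0))
})

test_that("detection is strict and the consensus is the intersection", {
  m <- rbind(a = c(10.0, 12, 12), b = c(10.5, 10.5, 10.5),
             c = c(11, 11, 9))
  d <- detect(m, threshold = 10)
  # 10.0 is not > 10
  expect_false("a" %in% d$per_replicate[[1]])
  expect_true("b" %in% d$consensus)
  # above threshold in 2 of 3: in those sets, not the consensus
  expect_true("c" %in% d$per_replicate[[1]])
  expect_false("c" %in% d$consensus)
})

test_that("detection inconsistency follows (U_X - U_123)/U_X * 100", {
  d <- structure(list(per_replicate = list(c("a", "b", "c"), c("a", "b"),
                                           c("a", "b")),
                      consensus = c("a", "b"), threshold = 10),
                 class = "detection_set")
  expect_equal(detection_inconsistency(d), c(100 / 3, 0, 0))

  ident <- detect(rbind(a = c(20, 20), b = c(30, 30)), 10)
  expect_equal(detection_inconsistency(ident), c(0, 0))

  disjoint <- structure(list(per_replicate = list("a", "b", "c"),
                             consensus = character(0), threshold = 10),
                        class = "detection_set")
  expect_equal(detection_inconsistency(disjoint), c(100, 100, 100))
})

test_that("false isomiRs are counted strictly above the threshold", {
  m <- matrix(c(100.0, 150, 99, 101), ncol = 1,
              dimnames = list(c("p1|AAA", "p1|AAC", "p2|GGG", "p2|GGT"),
                              "s1"))
  out <- false_isomirs(m, threshold = 100)
  expect_equal(out$s1$total_unique, 2)                # 100.0 excluded
  expect_equal(unname(out$s1$per_parent[c("p1", "p2")]), c(1L, 1L))
  expect_equal(unname(out$s1$expression["p1|AAC"]), 150)

  empty <- false_isomirs(matrix(numeric(0), 0, 1,
                                dimnames = list(NULL, "s1")))
  expect_equal(empty$s1$total_unique, 0)
})

test_that("MA statistics use log mean ratios after the >1 filter", {
  A <- cbind(r1 = c(x = 8, y = 40, z = 0.5), r2 = c(8, 40, 3))
  B <- cbind(r1 = c(x = 8, y = 80, z = 5), r2 = c(8, 80, 5))
  ma <- ma_statistics(A, B)
  # z fails the strict >1 filter in one sample of A
  expect_setequal(ma$feature, c("x", "y"))
  expect_equal(ma$M[ma$feature == "x"], 0)
  expect_equal(ma$M[ma$feature == "y"], -1)           # B = 2A
  expect_equal(ma$A[ma$feature == "y"], (log2(40) + log2(80)) / 2)
})

test_that("top-n overlap counts shared most-abundant features", {
  x <- stats::setNames(seq(100, 1, length.out = 30), paste0("f", 1:30))
  expect_equal(topn_overlap(list(a = x, b = x), n = 20)$global, 1)
  y <- stats::setNames(rev(x), names(x))
  expect_equal(topn_overlap(list(a = x, b = y), n = 10)$global, 0)
  # 6 shared of 20 gives 0.30
  z <- x
  names(z)[1:14] <- paste0("g", 1:14)
  ov <- topn_overlap(list(a = x, b = z), n = 20)
  expect_equal(ov$global, 6 / 20)
  expect_error(topn_overlap(list(a = x[1:5], b = x[1:5]), n = 20), "n exceeds")
})

test_that("batch error compares batch-1 means against batch 2", {
  b1 <- cbind(r1 = c(x = 100, y = 100, z = 9),
              r2 = c(100, 100, 50), r3 = c(100, 100, 50))
  b2 <- c(x = 100, y = 132, z = 50)
  be <- batch_error(b1, b2, filter_threshold = 10)
  expect_equal(unname(be["x"]), 0)
  expect_equal(unname(be["y"]), log2(33))
  expect_false("z" %in% names(be))   # fails the filter in one sample
})

test_that("triplicate error averages per-replicate deviations", {
  m <- rbind(flat = c(100, 100, 100), x = c(90, 100, 110))
  te <- triplicate_error(m)
  expect_equal(unname(te["flat"]), 0)
  expect_equal(unname(te["x"]), mean(c(log2(11), 0, log2(11))))
  expect_equal(unname(te["x"]), 2.306, tolerance = 1e-3)
})

test_that("starting-molecule estimation inverts expected amplification", {
  est <- estimate_starting_molecules(1e6, efficiency = 0.625, cycles = 18)
  expect_equal(est$n0, 1e6 / 1.625^18)
  expect_equal(est$n0, 160.2, tolerance = 1e-2)
  expect_false(est$saturating)
  expect_equal(estimate_starting_molecules(5000, cycles = 0)$n0, 5000)
  # approaching the 65,536-label UMI space flags saturation
  expect_true(estimate_starting_molecules(65536 * 0.25 * 1.625^18,
                                          0.625, 18)$saturating)

  # simulation round-trip: reads from amplified families recover the
  # starting molecule count within Monte-Carlo error
  pool <- toy_pool(n = 1)
  w <- selection_weights(pool, bias_model())
  model <- bias_model(pcr_efficiency_base = 0.625, pcr_cycles = 18)
  n0 <- vapply(1:5, function(s) {
    sm <- sample_molecules(pool, w, 100, umi_length_each_end = 4, seed = s)
    amp <- amplify(sm$molecules, model, seed = s + 50)
    estimate_starting_molecules(sum(amp$count), 0.625, 18)$n0
  }, numeric(1))
  expect_equal(mean(n0), 100, tolerance = 0.1)
})
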