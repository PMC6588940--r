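# Independent oracles used to check the package implementations.
# These are deliberately naive: plain enumeration and matrix reachability,
# sharing no code with the package internals.

# Enumerate every (5' offset, alignment) for one insert/reference pair and
# return the minimal policy cost, or Inf. Character-vector based, no
# shortcuts.
oracle_score <- function(insert, ref, max5 = 4, max3 = 4, maxmm = 2,
                         maxadd = 3) {
  ins <- strsplit(insert, "")[[1]]
  rf <- strsplit(ref, "")[[1]]
  best <- Inf
  for (o5 in seq(-max5, max5)) {
    ic <- if (o5 < 0) ins[-seq_len(-o5)] else ins
    rc <- if (o5 > 0) rf[-seq_len(o5)] else rf
    if (length(ic) < 1 || length(rc) < 1) next
    ov <- min(length(ic), length(rc))
    mm <- sum(ic[1:ov] != rc[1:ov])
    add <- max(0, length(ic) - length(rc))
    o3 <- max(0, length(rc) - length(ic))
    if (mm > maxmm || add > maxadd || o3 > max3) next
    best <- min(best, abs(o5) + o3 + mm + add)
  }
  best
}

oracle_assign <- function(insert, pool) {
  if (insert %in% pool$sequence) {
    return(list(parent_id = pool$id[match(insert, pool$sequence)],
                is_canonical = TRUE, cost = 0))
  }
  costs <- sapply(pool$sequence, function(r) oracle_score(insert, r))
  if (all(is.infinite(costs)))
    return(list(parent_id = NA_character_, is_canonical = FALSE,
                cost = NA_real_))
  winners <- pool$id[costs == min(costs)]
  list(parent_id = sort(winners)[1], is_canonical = FALSE,
       cost = min(costs))
}

# Brute-force directional UMI clustering: full Hamming matrix, directed
# adjacency, transitive closure by matrix powers, then greedy cluster
# assignment from count-sorted seeds.
oracle_directional <- function(counts) {
  umis <- names(counts)
  n <- length(umis)
  if (n == 1) return(1L)
  ham <- outer(umis, umis, Vectorize(function(a, b)
    sum(strsplit(a, "")[[1]] != strsplit(b, "")[[1]])))
  adj <- ham == 1 & outer(counts, counts, function(a, b) a >= 2 * b - 1)
  reach <- adj | diag(n) > 0
  for (k in seq_len(n)) reach <- reach | (reach %*% reach) > 0
  ord <- order(-counts, umis)
  assigned <- rep(FALSE, n)
  clusters <- 0L
  for (s in ord) {
    if (assigned[s]) next
    clusters <- clusters + 1L
    assigned[reach[s, ]] <- TRUE
  }
  clusters
}

# random UMI count sets for the clustering equivalence checks
random_umi_set <- function(max_umis = 8, width = 4) {
  k <- sample(1:max_umis, 1)
  umis <- unique(replicate(k, paste(sample(c("A", "C", "G", "T"), width,
                                           replace = TRUE), collapse = "")))
  stats::setNames(sample(1:20, length(umis), replace = TRUE), umis)
}

# n unique random DNA strings of a given width
random_dna_fixture <- function(n, width) {
  out <- character(0)
  while (length(out) < n)
    out <- unique(c(out, replicate(n, paste(
      sample(c("A", "C", "G", "T"), width, replace = TRUE), collapse = ""))))
  out[seq_len(n)]
}

# a tiny fixed pool useful across tests
toy_pool <- function(n = 6, seed = 99) build_reference_pool(n = n, seed = seed)

# sequential (type-I) sum-of-squares shares, fitted term by term
oracle_type1_ss <- function(response, factors) {
  dat <- data.frame(.y = response, factors, check.names = FALSE)
  terms <- names(factors)
  rss_prev <- sum((response - mean(response))^2)
  ss <- numeric(length(terms))
  for (i in seq_along(terms)) {
    fit <- stats::lm(stats::reformulate(terms[1:i], response = ".y"),
                     data = dat)
    rss_i <- sum(stats::residuals(fit)^2)
    ss[i] <- rss_prev - rss_i
    rss_prev <- rss_i
  }
  stats::setNames(ss, terms)
}
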