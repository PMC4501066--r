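test_that("read resampling preserves set sizes and the bootstrap exclusion rate", {
  expect_equal(resample_reads(list(a = "ACGT")), list(a = "ACGT"))
  set.seed(701)
  reads <- list(a = as.character(1:2000))
  rs <- resample_reads(reads)
  expect_equal(length(rs$a), 2000)
  # fraction of originals absent from a replicate ~ 1/e
  absent <- replicate(20, mean(!(reads$a %in% resample_reads(reads)$a)))
  expect_lt(abs(mean(absent) - exp(-1)), 3 * sd(absent) / sqrt(20) + 0.01)
  expect_error(resample_reads(list(a = character(0))), "no reads")
})

test_that("row resampling draws round(M/k) rows and valid pair counts", {
  set.seed(702)
  tabs <- count_tables_for(setNames(replicate(3, random_test_seq(600)),
                                    c("a", "b", "c")), 6)
  mg <- merge_kmer_tables(tabs)
  M <- nrow(mg$presence)
  rr <- resample_rows(mg, k = 6)
  expect_true(all(rr$ns <= rr$nt | rr$nt == 0))
  expect_equal(max(rr$nt), max(diag(rr$ns)))
  expect_lte(max(diag(rr$ns)), round(M / 6))
  # k = 1 reduces to the ordinary row bootstrap of full size
  rr1 <- resample_rows(mg, k = 1)
  expect_equal(sum(diag(rr1$ns) <= M), 3)
})

test_that("row-resampling variance approximates the evolutionary variance", {
  # two-species check: variance of D across row-bootstrap replicates vs the
  # spread across independent evolution replicates
  set.seed(703)
  g <- 3e4; k <- 11; d <- 0.1
  anc <- random_genome(g)
  sim_D <- replicate(60, {
    pr <- pair_at_distance(anc, d)
    sc <- shared_counts(count_kmers(pr[1], k, "a"), count_kmers(pr[2], k, "b"))
    kmer_distance(sc$n_s, sc$n_t, k)
  })
  pr <- pair_at_distance(anc, d)
  tabs <- count_tables_for(c(a = unname(pr[1]), b = unname(pr[2])), k)
  mg <- merge_kmer_tables(tabs)
  boot_D <- replicate(200, {
    rr <- resample_rows(mg, k)
    suppressWarnings(kmer_distance(rr$ns["a", "b"], rr$nt["a", "b"], k))
  })
  expect_lt(abs(var(boot_D) / var(sim_D) - 1), 0.5)
})

test_that("overlap weight follows its defining sum", {
  expect_equal(kmer_overlap_w(13, 13), 0)
  k <- 9; r <- 2 * k - 1
  expect_equal(kmer_overlap_w(k, r), sum(2 * (1:(k - 1))^2 / k^2))
  # direct summation oracle at another setting
  k <- 13; r <- 76
  i <- 1:(k - 1)
  expect_equal(kmer_overlap_w(k, r),
               sum(2 * i / (k * (r - k + 1)) * pmax(0, r - 2 * k + i + 1)))
})

test_that("evolutionary variance has its closed-form anchors", {
  expect_equal(evolutionary_variance(13, 1e5, 0), 0)
  for (D in c(0.05, 0.2)) {
    expect_equal(evolutionary_variance(1, 1e4, D), (exp(D) - 1) / 1e4)
    # and equals the reciprocal weight variance at k = 1
    expect_equal(evolutionary_variance(1, 1e4, D), 1 / wls_weight(D, 1, 1e4))
  }
  v <- evolutionary_variance(13, 1e5, c(0.05, 0.1, 0.2))
  expect_true(all(diff(v) > 0))
})

test_that("sampling sd is finite, positive, and scales with the inflation factor", {
  r <- observed_true_ratios(sampling_params(2, 76, 0.01, 13), 0.1)
  s1 <- sampling_sd(r, n_s = 2e4, sd_inflation = 1)
  s2 <- sampling_sd(r, n_s = 2e4, sd_inflation = 2)
  expect_gt(s1, 0)
  expect_equal(s2, 2 * s1)
  # more shared k-mers, less noise
  expect_lt(sampling_sd(r, n_s = 2e5), sampling_sd(r, n_s = 2e4))
})

test_that("shared-branch covariance matches a path-overlap oracle", {
  set.seed(704)
  tr <- ape::unroot(ape::rtree(6))
  tr$edge.length <- runif(nrow(tr$edge), 0.02, 0.2)
  taxa <- sort(tr$tip.label)
  n <- 6
  D <- ape::cophenetic.phylo(tr)[taxa, taxa]
  nt <- matrix(1e5, n, n, dimnames = list(taxa, taxa))
  M <- aaf_dist(D, nt, nt, 13)
  Sigma <- shared_branch_covariance(tr, M)
  pairs <- attr(Sigma, "pairs")
  k_idx <- function(a, b) which(pairs[, 1] == a & pairs[, 2] == b)
  # diagonal equals the evolutionary variance of each pair
  for (p in seq_len(nrow(pairs))) {
    i <- pairs[p, 1]; j <- pairs[p, 2]
    expect_equal(Sigma[p, p],
                 evolutionary_variance(13, nt[i, j], D[i, j]),
                 tolerance = 1e-10)
  }
  # off-diagonals proportional to the shared path length measured by ape
  for (rep in 1:10) {
    pq <- sample(nrow(pairs), 2)
    p <- pairs[pq[1], ]; q <- pairs[pq[2], ]
    s <- shared_path_oracle(tr, taxa[p[1]], taxa[p[2]], taxa[q[1]], taxa[q[2]])
    vp <- Sigma[pq[1], pq[1]] / D[p[1], p[2]]
    vq <- Sigma[pq[2], pq[2]] / D[q[1], q[2]]
    expect_equal(Sigma[pq[1], pq[2]], s * sqrt(vp * vq), tolerance = 1e-8)
  }
  # a quartet with disjoint paths has zero covariance
  q4 <- ape::read.tree(text = "((a:1,b:1):1,(c:1,d:1):1);")
  taxa4 <- c("a", "b", "c", "d")
  D4 <- ape::cophenetic.phylo(q4)[taxa4, taxa4]
  nt4 <- matrix(1e4, 4, 4, dimnames = list(taxa4, taxa4))
  S4 <- shared_branch_covariance(q4, aaf_dist(D4, nt4, nt4, 13))
  p4 <- attr(S4, "pairs")
  ab <- which(p4[, 1] == 1 & p4[, 2] == 2)
  cd <- which(p4[, 1] == 3 & p4[, 2] == 4)
  expect_equal(S4[ab, cd], 0, tolerance = 1e-12)
})

test_that("bootstraps are deterministic under a fixed seed", {
  set.seed(705)
  tr <- ape::read.tree(text = "((a:0.03,b:0.03):0.03,(c:0.03,d:0.03):0.03);")
  seqs <- evolve_on_tree(random_genome(4000), tr)
  reads <- lapply(seqs, simulate_reads, coverage = 6, read_length = 40,
                  error_rate = 0.01)
  b1 <- nonparametric_bootstrap(reads, k = 9, B = 5, seed = 11)
  b2 <- nonparametric_bootstrap(reads, k = 9, B = 5, seed = 11)
  expect_identical(b1$support, b2$support)
  expect_identical(ape::write.tree(b1$tree), ape::write.tree(b2$tree))

  tabs <- count_tables_for(seqs, 9)
  M <- kmer_distance_matrix(tabs)
  fit <- fit_tree(M)
  pars <- lapply(setNames(names(seqs), names(seqs)), function(i)
    sampling_params(6, 40, 0.01, 9))
  p1 <- parametric_bootstrap(M, fit, pars, B = 8, seed = 12)
  p2 <- parametric_bootstrap(M, fit, pars, B = 8, seed = 12)
  expect_identical(p1$support, p2$support)
})

test_that("vanishing stage-1 noise saturates stage-1 support", {
  set.seed(706)
  tr <- ape::read.tree(
    text = "((a:0.05,b:0.05):0.05,(c:0.05,d:0.05):0.05,e:0.1);")
  seqs <- evolve_on_tree(random_genome(8000), tr)
  tabs <- count_tables_for(seqs, 11)
  M <- kmer_distance_matrix(tabs)
  fit <- fit_tree(M)
  pars <- lapply(setNames(names(seqs), names(seqs)), function(i)
    sampling_params(10, 70, 0.01, 11))
  bb <- parametric_bootstrap(M, fit, pars, B = 10, seed = 3,
                             sd_inflation = 1e-8)
  expect_true(all(bb$support$stage1 == 10))
  # stage 2 carries evolutionary noise on top: support can only drop
  expect_true(all(bb$support$stage2 <= bb$support$stage1))
})
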