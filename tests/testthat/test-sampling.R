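test_that("coverage retention follows the Poisson read-start model", {
  p0 <- sampling_params(0, 76, 0.01, 13)
  expect_equal(coverage_retention(p0), 0)
  expect_equal(coverage_retention(sampling_params(0, 76, 0.01, 13,
                                                  filtered = TRUE)), 0)
  p <- sampling_params(5, 76, 0, 17)
  pf <- sampling_params(5, 76, 0, 17, filtered = TRUE)
  expect_equal(p$L, 5 * 60 / 76)
  expect_equal(coverage_retention(p), 1 - exp(-p$L))
  expect_equal(coverage_retention(pf), 1 - (1 + p$L) * exp(-p$L))
  # unfiltered minus filtered = L e^-L >= 0
  expect_equal(coverage_retention(p) - coverage_retention(pf),
               p$L * exp(-p$L))
})

test_that("error retention equals the ratio of Poisson tail probabilities", {
  for (cv in c(1, 3, 8)) {
    pu <- sampling_params(cv, 76, 0.01, 13)
    pf <- sampling_params(cv, 76, 0.01, 13, filtered = TRUE)
    expect_equal(error_retention(pu),
                 ppois(0, pu$lambda, lower.tail = FALSE) /
                   ppois(0, pu$L, lower.tail = FALSE))
    expect_equal(error_retention(pf),
                 ppois(1, pf$lambda, lower.tail = FALSE) /
                   ppois(1, pf$L, lower.tail = FALSE))
    # the direct (non-simplified) filtered expression agrees
    L <- pf$L; lam <- pf$lambda; E <- pf$E; k <- pf$k
    direct <- 1 - (exp(-lam) - (1 + L) * exp(-L)) / (1 - (1 + L) * exp(-L)) -
      (1 - E)^k * L * exp(-lam) / (1 - (1 + L) * exp(-L))
    expect_equal(error_retention(pf), direct, tolerance = 1e-12)
  }
  expect_equal(error_retention(sampling_params(5, 76, 0, 13)), 1)
  expect_equal(error_retention(sampling_params(5, 76, 0, 13, filtered = TRUE)), 1)
})

test_that("false k-mer rates match their closed forms", {
  expect_equal(false_kmer_rates(sampling_params(5, 76, 0, 13)),
               list(p_ta = 0, p_sa = 0))
  expect_equal(false_kmer_rates(sampling_params(5, 76, 0.01, 13,
                                                filtered = TRUE), d = 0.1),
               list(p_ta = 0, p_sa = 0))
  fr <- false_kmer_rates(sampling_params(5, 76, 0.01, 13), d = 0.1)
  L <- 5 * 64 / 76
  expect_equal(fr$p_ta, L * (1 - 0.99^13))
  expect_equal(fr$p_ta, 0.516, tolerance = 0.002)
  expect_equal(fr$p_sa, L * (1 - (1 - 0.01 / 3)^(13 * 0.1)))
})

test_that("observed/true ratios compose correctly with their limits", {
  hi <- observed_true_ratios(sampling_params(60, 76, 0, 15))
  expect_equal(hi$p_t, 1, tolerance = 1e-10)
  expect_equal(hi$p_s, 1, tolerance = 1e-10)
  # false k-mers build up from 2X and push totals beyond one by 3X,
  # unfiltered
  expect_gt(observed_true_ratios(sampling_params(2, 76, 0.01, 13), 0.1)$p_ta,
            0.15)
  expect_gt(observed_true_ratios(sampling_params(3, 76, 0.01, 13), 0.1)$p_t, 1)
  # filtering restores p_t -> 1 at high coverage
  expect_equal(observed_true_ratios(sampling_params(30, 76, 0.01, 13,
                                                    filtered = TRUE), 0.1)$p_t,
               1, tolerance = 1e-4)
  r <- observed_true_ratios(sampling_params(3, 76, 0.01, 13), 0.1)
  expect_equal(r$p_t, r$q_t + r$p_ta)
  expect_equal(r$p_s, r$q_s + r$p_sa)
  expect_equal(r$q_s, r$q_t^2)
})

test_that("distance bias is the log ratio of the count ratios", {
  r <- observed_true_ratios(sampling_params(3, 76, 0.01, 13), 0.1)
  expect_equal(distance_bias(r), -log(r$p_s / r$p_t) / 13)
  r0 <- observed_true_ratios(sampling_params(50, 76, 0, 13))
  expect_equal(distance_bias(r0), 0, tolerance = 1e-10)
  # bias non-negative whenever shared losses dominate
  if (r$p_s <= r$p_t) expect_gte(distance_bias(r), 0)
})

test_that("sampling variance shrinks with coverage and with n_s", {
  v <- vapply(c(1, 2, 5, 10, 20), function(cv)
    distance_variance(observed_true_ratios(
      sampling_params(cv, 76, 0.01, 13), 0.1), n_s = 2e4), numeric(1))
  expect_true(all(diff(v) < 0))
  r <- observed_true_ratios(sampling_params(5, 76, 0.01, 13), 0.1)
  expect_lt(distance_variance(r, 1e7), distance_variance(r, 1e4))
  expect_lt(distance_variance(r, 1e9), 1e-9)
  # the documented n_t variant changes only the second term's denominator
  expect_gt(distance_variance(r, 1e4, n_t = 1e3, nt_variant = TRUE),
            distance_variance(r, 1e4))
})

test_that("filtered-vs-unfiltered variance crossover sits between 5X and 8X", {
  for (k in c(11, 13, 15)) {
    gap <- function(cv) {
      distance_variance(observed_true_ratios(
        sampling_params(cv, 76, 0.01, k, filtered = TRUE), 0.1), 2e4) -
        distance_variance(observed_true_ratios(
          sampling_params(cv, 76, 0.01, k), 0.1), 2e4)
    }
    expect_gt(gap(5), 0)   # filtering worse at 5X
    expect_lt(gap(8), 0)   # filtering better at 8X
    expect_lt(uniroot(gap, c(5, 8))$root, 8)
  }
})

test_that("tip correction matches the closed-form arithmetic and its limits", {
  expect_equal(tip_correction(sampling_params(2, 70, 0.01, 21)), 0.017,
               tolerance = 0.01)
  expect_equal(tip_correction(sampling_params(500, 70, 0, 21)), 0,
               tolerance = 1e-8)
  # filtered variant reduces to -(1/2k) log(p_rf p_ef)
  pf <- sampling_params(5, 76, 0.01, 13, filtered = TRUE)
  expect_equal(tip_correction(pf),
               -log(coverage_retention(pf) * error_retention(pf)) / (2 * 13))
})

test_that("heterogeneous-taxa correction averages the lower-n_t pair values", {
  pars <- list(a = sampling_params(2, 70, 0.01, 13),
               b = sampling_params(2, 70, 0.01, 13),
               c = sampling_params(2, 70, 0.01, 13))
  nt <- c(a = 1e5, b = 1e5, c = 1e5)
  one <- tip_correction(pars$a)
  expect_equal(average_tip_correction(pars, nt),
               c(a = one, b = one, c = one))
  # two classes: enumerate pairs by hand
  pars2 <- list(a = sampling_params(2, 70, 0.01, 13),
                b = sampling_params(10, 70, 0.01, 13),
                c = sampling_params(10, 70, 0.01, 13))
  nt2 <- c(a = 5e4, b = 1e5, c = 1e5)
  lo <- tip_correction(pars2$a)   # pairs ab, ac take a's params
  hihi <- tip_correction(pars2$b) # pair bc
  expected <- mean(c(lo, lo, hihi))
  expect_equal(unname(average_tip_correction(pars2, nt2)), rep(expected, 3))
})

test_that("retention and false rates match a Monte-Carlo read simulation", {
  set.seed(501)
  g <- 3e4; k <- 13; r <- 76
  genome <- random_genome(g)
  true_tab <- count_kmers(genome, k, "truth")
  true_keys <- names(kmer_counts(true_tab))
  one_rep <- function(cv, E, filt) {
    tab <- count_kmers(simulate_reads(genome, cv, r, E), k, "obs",
                       filter_singletons = filt)
    obs <- names(kmer_counts(tab))
    c(ret = mean(true_keys %in% obs),
      false_rate = sum(!(obs %in% true_keys)) / length(true_keys))
  }
  for (cv in c(2, 5)) {
    reps <- t(replicate(5, one_rep(cv, 0.01, FALSE)))
    rates <- observed_true_ratios(sampling_params(cv, r, 0.01, k), 0)
    expect_lt(abs(mean(reps[, "ret"]) - rates$q_t),
              3 * sd(reps[, "ret"]) / sqrt(5) + 0.003)
    expect_lt(abs(mean(reps[, "false_rate"]) - rates$p_ta),
              3 * sd(reps[, "false_rate"]) / sqrt(5) + 0.01)
    repsf <- t(replicate(5, one_rep(cv, 0.01, TRUE)))
    ratesf <- observed_true_ratios(sampling_params(cv, r, 0.01, k,
                                                   filtered = TRUE), 0)
    # additive guard covers the linear-genome edge effect (read starts are
    # confined to g - r + 1 positions) that the closed form ignores
    expect_lt(abs(mean(repsf[, "ret"]) - ratesf$q_t),
              3 * sd(repsf[, "ret"]) / sqrt(5) + 0.006)
  }
})
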