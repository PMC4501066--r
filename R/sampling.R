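#' Per-taxon sequencing parameters
#'
#' Bundles the quantities that drive every coverage/error correction:
#' sequencing depth `c` (fold coverage), read length `r` (bp; use the mean
#' when lengths vary), per-base error rate `E`, k-mer length `k`, and the
#' singleton-filter flag. Two derived rates are attached: `L = c (r - k + 1) / r`,
#' the expected number of read starts that span a given k-mer locus, and
#' `lambda = L (1 - E)^k`, the expected number of *error-free* observations
#' of that locus.
#'
#' @param coverage fold coverage `c`.
#' @param read_length read length `r` in bp.
#' @param error_rate per-base error rate `E`, in [0, 1).
#' @param k k-mer length (must be smaller than the read length).
#' @param filtered singleton filtering in effect.
#' @return object of class `aaf_sampling_params`.
#' @export
sampling_params <- function(coverage, read_length = 70, error_rate = 0.01,
                            k, filtered = FALSE) {
  stopifnot(coverage >= 0, read_length > k, error_rate >= 0, error_rate < 1)
  L <- coverage * (read_length - k + 1) / read_length
  structure(list(c = coverage, r = read_length, E = error_rate,
                 k = k, filtered = filtered,
                 L = L, lambda = L * (1 - error_rate)^k),
            class = "aaf_sampling_params")
}

#' Probability that a true k-mer is covered at all
#'
#' With Poisson read starts at rate `L` per k-mer locus, a k-mer is seen at
#' least once with probability `1 - e^{-L}`; if singletons are filtered it
#' must be seen at least twice, `1 - (1 + L) e^{-L}`.
#'
#' @param params an [sampling_params()].
#' @return retention probability (`p_r` unfiltered, `p_rf` filtered).
#' @export
coverage_retention <- function(params) {
  L <- params$L
  if (params$filtered) -expm1(-L) - L * exp(-L) else -expm1(-L)
}

#' Probability that a covered true k-mer survives sequencing error
#'
#' Conditional on being covered, a k-mer is retained if enough of its
#' observations are error-free: each observation is clean with probability
#' `(1 - E)^k`, thinning the Poisson rate from `L` to `lambda`. Unfiltered,
#' the retention is `P(Pois(lambda) >= 1) / P(Pois(L) >= 1)`; filtered,
#' `P(Pois(lambda) >= 2) / P(Pois(L) >= 2)` (the algebraic simplification
#' of the two-copy requirement).
#'
#' @param params an [sampling_params()].
#' @return retention probability (`p_e` unfiltered, `p_ef` filtered).
#' @export
error_retention <- function(params) {
  L <- params$L; lam <- params$lambda
  if (params$filtered) {
    (-expm1(-lam) - lam * exp(-lam)) / (-expm1(-L) - L * exp(-L))
  } else {
    -expm1(-lam) / -expm1(-L)
  }
}

#' Rates of error-born false k-mers
#'
#' Sequencing errors mint k-mers that are not in the genome. Per true k-mer
#' locus, the expected number of distinct false k-mers is
#' `p_ta = L (1 - (1 - E)^k)`; the rate at which an error reproduces a
#' k-mer of the *other* genome (creating false sharing) is
#' `p_sa = L (1 - (1 - E/3)^{k d})`, which needs a provisional distance
#' `d`. With singleton filtering both rates are vanishingly small and are
#' returned as zero.
#'
#' @param params an [sampling_params()].
#' @param d provisional pairwise distance (for `p_sa`).
#' @return list with `p_ta` and `p_sa`.
#' @export
false_kmer_rates <- function(params, d = 0) {
  stopifnot(d >= 0)
  if (params$filtered) return(list(p_ta = 0, p_sa = 0))
  L <- params$L; E <- params$E; k <- params$k
  list(p_ta = L * (1 - (1 - E)^k),
       p_sa = L * (1 - (1 - E / 3)^(k * d)))
}

#' Observed-to-true k-mer count ratios
#'
#' Composes retention and false-k-mer rates into the ratios of observed to
#' true counts: `p_t = n_t*/n_t = q_t + p_ta` and
#' `p_s = n_s*/n_s = q_s + p_sa`, where `q_t = p_r p_e` and
#' `q_s = (p_r p_e)^2` are the joint retention of a true k-mer in one and in
#' both genomes (filtered variants substituted when `params$filtered`).
#' `p_t` may exceed 1 — false k-mers inflate totals.
#'
#' @param params an [sampling_params()] (assumed shared by the pair).
#' @param d provisional pairwise distance for the false-sharing rate.
#' @return object of class `aaf_sampling_rates`: list with `p_cov`
#'   (`p_r`/`p_rf`), `p_err` (`p_e`/`p_ef`), `q_t`, `q_s`, `p_ta`, `p_sa`,
#'   `p_t`, `p_s` and the originating `params`.
#' @export
observed_true_ratios <- function(params, d = 0) {
  p_cov <- coverage_retention(params)
  p_err <- error_retention(params)
  fr <- false_kmer_rates(params, d)
  q_t <- p_cov * p_err
  q_s <- q_t^2
  structure(list(p_cov = p_cov, p_err = p_err, q_t = q_t, q_s = q_s,
                 p_ta = fr$p_ta, p_sa = fr$p_sa,
                 p_t = q_t + fr$p_ta, p_s = q_s + fr$p_sa,
                 params = params),
            class = "aaf_sampling_rates")
}

#' Distance bias from incomplete coverage and sequencing error
#'
#' The observed-data distance overshoots the true one by
#' `D* - D = -(1/k) log(p_s / p_t)`, non-negative whenever shared k-mers
#' are lost faster than totals.
#'
#' @param rates an [observed_true_ratios()] result.
#' @return additive bias on the distance scale.
#' @export
distance_bias <- function(rates) {
  stopifnot(inherits(rates, "aaf_sampling_rates"))
  -log(rates$p_s / rates$p_t) / rates$params$k
}

#' Sampling variance of the distance estimate
#'
#' Variance of `log(n_s*/n_t*)` caused by read sampling and errors alone
#' (the genomes held fixed):
#' `log(1 + (1/n_s)(q_s(1-q_s)+p_sa)/(q_s+p_sa)^2) +
#'  log(1 + (1/n_s)(q_t(1-q_t)+p_ta)/(q_t+p_ta)^2)`,
#' divided by `k^2` to give the variance of `D*`. The second term is
#' evaluated with a `1/n_s` factor; `nt_variant = TRUE` switches
#' it to `1/n_t` for users who prefer the symmetric reading.
#'
#' @param rates an [observed_true_ratios()] result.
#' @param n_s true shared k-mer count of the pair.
#' @param n_t true total k-mer count (only used when `nt_variant`).
#' @param nt_variant use `1/n_t` in the second term.
#' @return variance of the distance estimate.
#' @export
distance_variance <- function(rates, n_s, n_t = n_s, nt_variant = FALSE) {
  stopifnot(inherits(rates, "aaf_sampling_rates"), n_s > 0)
  q_s <- rates$q_s; q_t <- rates$q_t
  t1 <- log1p((q_s * (1 - q_s) + rates$p_sa) / (q_s + rates$p_sa)^2 / n_s)
  n2 <- if (nt_variant) n_t else n_s
  t2 <- log1p((q_t * (1 - q_t) + rates$p_ta) / (q_t + rates$p_ta)^2 / n2)
  (t1 + t2) / rates$params$k^2
}

#' Tip correction for coverage/error distance inflation
#'
#' Half the distance bias attributable to one taxon:
#' `D_tip = (1/2k) log((p_r p_e + p_ta) / (p_r p_e)^2)` (filtered variants
#' substituted, with zero false rate). Deliberately excludes the
#' false-sharing term so the correction does not depend on the unknown true
#' distance. Subtract it from each terminal branch *after* the topology has
#' been fitted (the fit's weights refer to the uncorrected observations).
#'
#' @param params an [sampling_params()].
#' @return tip correction on the distance scale.
#' @export
tip_correction <- function(params) {
  rates <- observed_true_ratios(params, d = 0)
  log((rates$q_t + rates$p_ta) / rates$q_s) / (2 * params$k)
}

#' Averaged tip correction for heterogeneous taxa
#'
#' When coverage, read length or error rate differ among taxa, compute for
#' every pair the correction from the taxon with the smaller `n_t` (the one
#' whose sampling drives the pair's shared counts) and trim every tip by
#' the mean over all pairs.
#'
#' @param params_list named list of [sampling_params()], one per taxon.
#' @param n_t named numeric vector of per-taxon distinct k-mer totals.
#' @return named vector of per-taxon corrections (all equal to the
#'   pair-averaged value).
#' @export
average_tip_correction <- function(params_list, n_t) {
  taxa <- names(params_list)
  stopifnot(length(taxa) >= 2, !is.null(taxa), all(taxa %in% names(n_t)))
  prs <- combn(taxa, 2)
  per_pair <- apply(prs, 2, function(pr) {
    lower <- pr[which.min(n_t[pr])]
    tip_correction(params_list[[lower]])
  })
  setNames(rep(mean(per_pair), length(taxa)), taxa)
}
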