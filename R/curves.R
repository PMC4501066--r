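#' Homoplasy diagnostic curves
#'
#' Evaluates the random-genome shared-k-mer prediction over a grid of
#' genome sizes, GC contents and distances, together with the
#' no-homoplasy baseline `exp(-k d)`. Plotting `p_h` against the baseline
#' is the standard way to pick the smallest safe k for a dataset.
#'
#' @param g genome lengths (bp).
#' @param u GC contents.
#' @param d distances.
#' @param k_range k values to evaluate.
#' @return data.frame with columns `k`, `g`, `u`, `d`, `p_h`, `baseline`,
#'   `excess` (relative excess of `p_h` over the baseline).
#' @export
homoplasy_curves <- function(g = c(1e5, 1e7, 1e9), u = 0.5,
                             d = c(0.02, 0.1), k_range = 7:31) {
  grid <- expand.grid(k = k_range, g = g, u = u, d = d,
                      KEEP.OUT.ATTRS = FALSE)
  res <- mapply(function(k, g, u, d) {
    hp <- shared_kmer_prob_random(g, u, k, d)
    c(hp$p_h, hp$baseline)
  }, grid$k, grid$g, grid$u, grid$d)
  grid$p_h <- res[1, ]
  grid$baseline <- res[2, ]
  grid$excess <- grid$p_h / grid$baseline - 1
  grid
}

#' Coverage/error diagnostic curves
#'
#' Tabulates the observed-to-true count ratios, distance bias and
#' sampling variance over a coverage grid, for filtered and unfiltered
#' counting.
#'
#' @param coverage fold-coverage grid.
#' @param k k-mer lengths.
#' @param read_length read length (bp).
#' @param error_rate per-base error rate.
#' @param d distance used for the false-sharing rate.
#' @param n_s shared k-mer count used for the variance column.
#' @return data.frame with columns `coverage`, `k`, `filtered`, `p_t`,
#'   `p_s`, `bias`, `variance`, `tip_correction`.
#' @export
sampling_curves <- function(coverage = seq(0.5, 20, by = 0.5),
                            k = c(9, 11, 13, 15, 17), read_length = 76,
                            error_rate = 0.01, d = 0.1, n_s = 1e5) {
  grid <- expand.grid(coverage = coverage, k = k,
                      filtered = c(FALSE, TRUE), KEEP.OUT.ATTRS = FALSE)
  res <- mapply(function(cv, kk, fl) {
    p <- sampling_params(cv, read_length, error_rate, kk, fl)
    rt <- observed_true_ratios(p, d)
    c(rt$p_t, rt$p_s, distance_bias(rt), distance_variance(rt, n_s),
      tip_correction(p))
  }, grid$coverage, grid$k, grid$filtered)
  grid$p_t <- res[1, ]
  grid$p_s <- res[2, ]
  grid$bias <- res[3, ]
  grid$variance <- res[4, ]
  grid$tip_correction <- res[5, ]
  grid
}
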