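#' Probability that two random genomic locations carry the same k-mer
#'
#' With GC content `u`, a random k-mer matches another random location (on
#' either strand) with probability `2 (0.5 - u + u^2)^k`; the minimum is at
#' `u = 0.5`, where it equals `2 * 4^-k`. Biased composition inflates it.
#'
#' @param u GC content, in (0, 1).
#' @param k k-mer length.
#' @return matching probability.
#' @export
match_probability <- function(u, k) {
  stopifnot(u > 0, u < 1)
  2 * (0.5 - u + u^2)^k
}

#' Number of distinct canonical k-mers
#'
#' The size of canonical k-mer space, accounting for reverse-complement
#' identification: `4^k / 2` for odd `k` (no k-mer equals its own reverse
#' complement), and `(4^k + 4^{k/2}) / 2` for even `k` (self-complementary
#' palindromes collapse to themselves).
#'
#' @param k k-mer length.
#' @param exact include the even-`k` palindrome correction (otherwise the
#'   plain `4^k/2` approximation is returned).
#' @return count (double).
#' @export
canonical_kmer_count <- function(k, exact = TRUE) {
  if (exact && k %% 2 == 0) (4^k + 4^(k / 2)) / 2 else 4^k / 2
}

p_h_combine <- function(p1, p2, p3, k, d) {
  structure(list(p1 = p1, p2 = p2, p3 = p3,
                 p_h = p1 + (1 - p1) * p2 + (1 - p1) * (1 - p2) * p3,
                 baseline = exp(-k * d)),
            class = "aaf_homoplasy")
}

#' @export
print.aaf_homoplasy <- function(x, ...) {
  cat(sprintf("p_h = %.6g (no-homoplasy baseline %.6g; p1 = %.4g, p2 = %.4g, p3 = %.4g)\n",
              x$p_h, x$baseline, x$p1, x$p2, x$p3))
  invisible(x)
}

# (1 - x)^g evaluated stably in log space.
pow1m <- function(x, g) exp(g * log1p(-x))

#' Shared-k-mer probability for random genomes
#'
#' Closed-form prediction of the expected ratio `n_s/n_t` between two
#' genomes at distance `d`, when the ancestral genome is an i.i.d. random
#' sequence of length `g` with GC content `u`. Three inflation channels are
#' combined: `p1` (at least one of the multiple copies of a k-mer escapes
#' mutation), `p2` (a mutated k-mer is regenerated by a mutation elsewhere),
#' and `p3` (a mutated k-mer coincides with a k-mer already present
#' elsewhere). Without homoplasy the ratio would be `exp(-k d)`.
#'
#' Copy numbers of a k-mer in a random genome are Binomial(`g`, `P`) with
#' `P` from [match_probability()]; the closed forms below are the
#' expectations of the per-copy escape terms under that distribution,
#' conditioned on presence. Powers `(1-x)^g` are evaluated in log space and
#' are stable up to `g = 1e10`.
#'
#' @param g genome length (bp) of the shorter genome.
#' @param u GC content.
#' @param k k-mer length.
#' @param d true distance between the two genomes.
#' @return object of class `aaf_homoplasy` with fields `p1`, `p2`, `p3`,
#'   `p_h` and `baseline` (`exp(-k d)`).
#' @export
shared_kmer_prob_random <- function(g, u = 0.5, k, d) {
  stopifnot(g >= 1, d >= 0)
  P <- match_probability(u, k)
  e <- exp(-k * d)
  # (1-x)^g - 1 via expm1 keeps differences of near-one powers exact even
  # when g*P is far below double precision
  em <- function(x) expm1(g * log1p(-x))
  den <- -em(P)                           # 1 - (1-P)^g
  p1 <- 1 - (em(P * e) - em(P)) / den
  p2 <- (1 - e) * den
  x3 <- P * pow1m(P, g)                   # P (1-P)^g
  p3 <- 0.5 * e * (em(x3) - em(P)) / den
  p_h_combine(p1, p2, p3, k, d)
}

#' Shared-k-mer probability from an empirical copy-number spectrum
#'
#' Same prediction as [shared_kmer_prob_random()] but with the per-genome
#' copy-number distribution taken from data (a [kmer_spectrum()] of the
#' shorter genome, computed without filtering) instead of the random-genome
#' binomial. The escape sums use the total copy number `j >= 1` as the
#' exponent: `1 - p1 = sum_j (1 - e^{-kd})^j q[j]`, and similarly for `p3`;
#' this convention is the one that collapses to the random-genome closed
#' form when the spectrum is Binomial(`g`, `P`).
#'
#' @param spectrum an `aaf_spectrum` (from an unfiltered table).
#' @param g genome length of the shorter genome.
#' @param u GC content.
#' @param d true (or provisional) distance.
#' @return `aaf_homoplasy` object.
#' @export
shared_kmer_prob_empirical <- function(spectrum, g, u = 0.5, d) {
  stopifnot(inherits(spectrum, "aaf_spectrum"))
  if (d < 0) stop("d must be non-negative")
  k <- spectrum$k
  q <- spectrum$q
  j <- seq_along(q)
  P <- match_probability(u, k)
  e <- exp(-k * d)
  x <- 1 - e
  p1 <- 1 - sum(x^j * q)
  den <- -expm1(g * log1p(-P))
  p2 <- x * den
  y <- den                                # 1 - (1-P)^g
  p3 <- 0.5 * e * sum(y^j * q)
  p_h_combine(p1, p2, p3, k, d)
}

#' Smallest k with negligible k-mer homoplasy
#'
#' Scans `k` upward and returns the first value whose predicted homoplasy
#' excess `p_h / exp(-k d) - 1` stays below `tol` for every distance up to
#' `d_max`. The default tolerance (0.05) is calibrated on the random-genome
#' model so that a 1 Gbp genome at `u = 0.5` yields `k = 19`, the scale at
#' which homoplasy becomes negligible for genomes of that size. With an
#' empirical spectrum the same scan uses the observed k-mer copy-number
#' distributions (one spectrum per candidate `k`).
#'
#' @param g genome length (bp).
#' @param d_max largest distance expected in the data (run a quick
#'   large-`k` pass with [kmer_distance()] to get a conservative value).
#' @param u GC content.
#' @param tol maximum tolerated relative excess of `p_h` over the
#'   no-homoplasy baseline.
#' @param k_range candidate k values, scanned in increasing order.
#' @param spectra optional named list of `aaf_spectrum` objects keyed by
#'   `k`; when supplied, candidates are restricted to these k and the
#'   empirical prediction is used.
#' @return the recommended k (integer).
#' @export
select_k <- function(g, d_max = 0.1, u = 0.5, tol = 0.05, k_range = 5:31,
                     spectra = NULL) {
  stopifnot(tol > 0, d_max > 0)
  d_grid <- unique(pmin(d_max, c(0.01, 0.02, 0.05, 0.1, d_max)))
  if (!is.null(spectra))
    k_range <- sort(as.integer(names(spectra)))
  for (k in sort(k_range)) {
    excess <- vapply(d_grid, function(d) {
      hp <- if (is.null(spectra))
        shared_kmer_prob_random(g, u, k, d)
      else
        shared_kmer_prob_empirical(spectra[[as.character(k)]], g, u, d)
      hp$p_h / hp$baseline - 1
    }, numeric(1))
    if (max(excess) < tol) return(as.integer(k))
  }
  stop("no k in the scanned range keeps homoplasy below tol = ", tol,
       "; inspect homoplasy_curves() and consider larger k")
}
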