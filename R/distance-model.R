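#' Substitution model for the back-substitution correction
#'
#' Holds the per-event transition probability `w_s` and per-target
#' transversion probability `w_t` (two transversion targets per nucleotide,
#' so `w_s + 2 w_t = 1`), and the derived no-net-change probabilities
#' `gamma_m` after m substitutions at one site: `gamma_0 = 1`, `gamma_1 = 0`,
#' `gamma_2 = w_s^2 + 2 w_t^2`, `gamma_3 = 2 w_s^2 w_t + 4 w_t^3`. Terms
#' beyond m = 3 are negligible at the distances where the method applies.
#'
#' @param w_s probability that a substitution is a transition.
#' @param w_t probability of each of the two transversion targets.
#' @return object of class `aaf_subst_model`.
#' @export
substitution_model <- function(w_s = 0.5, w_t = 0.25) {
  if (abs(w_s + 2 * w_t - 1) > 1e-8)
    warning("w_s + 2*w_t != 1; probabilities do not sum over the three targets")
  structure(list(
    w_s = w_s, w_t = w_t,
    gamma = c(1, 0, w_s^2 + 2 * w_t^2, 2 * w_s^2 * w_t + 4 * w_t^3)),
    class = "aaf_subst_model")
}

#' Distance from shared/total k-mer counts
#'
#' The core estimator: `D = -(1/k) log(n_s / n_t)`, where `n_s` is the
#' number of shared distinct k-mers and `n_t` the smaller of the two taxa's
#' totals. `n_s = 0` (no sharing at all) is capped with a half-count
#' continuity correction, `D = -(1/k) log(0.5 / n_t)`, with a warning.
#'
#' @param n_s shared distinct k-mers (scalar or vector).
#' @param n_t total distinct k-mers (smaller of the pair).
#' @param k k-mer length.
#' @return distance estimate(s) in expected mutations per site.
#' @export
kmer_distance <- function(n_s, n_t, k) {
  if (any(n_t <= 0)) stop("n_t must be positive")
  if (any(n_s > n_t)) stop("n_s cannot exceed n_t")
  if (any(n_s < 0)) stop("n_s must be non-negative")
  zero <- n_s == 0
  if (any(zero)) {
    warning("degenerate pair(s) with n_s = 0: distance capped at -log(0.5/n_t)/k")
    n_s[zero] <- 0.5
  }
  -log(n_s / n_t) / k
}

#' Expected shared-k-mer ratio under the back-substitution series
#'
#' Forward model: the probability that one site shows no net change across
#' distance `d` is `sum_m gamma_m d^m e^{-d}/m!` (series truncated at
#' m = 3); raising it to the k gives the expected `n_s/n_t`.
#'
#' @param d true distance (mutations per site).
#' @param k k-mer length.
#' @param model an [substitution_model()].
#' @return expected ratio `n_s/n_t`.
#' @export
backsub_ratio <- function(d, k, model = substitution_model()) {
  m <- 0:3
  site <- vapply(d, function(di)
    sum(model$gamma * di^m * exp(-di) / factorial(m)), numeric(1))
  site^k
}

#' Distance corrected for back substitutions
#'
#' Inverts the back-substitution series by bracketed root finding on
#' `[0, d_max]` to tolerance 1e-10. At the distances where k-mer methods are
#' reliable (d <= 0.2) the correction relative to [kmer_distance()] stays
#' below ~4%, which is why the plain estimator is the pipeline default.
#'
#' @param ratio observed `n_s/n_t`, in (0, 1].
#' @param k k-mer length.
#' @param model an [substitution_model()].
#' @param d_max upper bracket for the root search.
#' @return corrected distance estimate.
#' @export
kmer_distance_backsub <- function(ratio, k, model = substitution_model(),
                                  d_max = 2) {
  if (any(ratio <= 0) || any(ratio > 1))
    stop("ratio must be in (0, 1]")
  vapply(ratio, function(r) {
    if (r == 1) return(0)
    f <- function(d) backsub_ratio(d, k, model) - r
    if (f(d_max) > 0)
      stop("no root in [0, ", d_max, "] for ratio ", r)
    uniroot(f, c(0, d_max), tol = 1e-10)$root
  }, numeric(1))
}

#' Inverse-variance weight for the weighted least-squares fit
#'
#' The sampling variance of a distance estimate is approximately
#' `(1/n_t) (1 - e^{-k D}) / e^{-k D}`; the fit weights each pair by the
#' reciprocal, `w = n_t e^{-k D} / (1 - e^{-k D})`, so noisy long distances
#' are down-weighted. `D_hat` is floored at `eps` to avoid an infinite
#' weight at zero distance.
#'
#' @param D_hat fitted distance(s).
#' @param k k-mer length.
#' @param n_t total distinct k-mers for the pair.
#' @param eps floor applied to `D_hat`.
#' @return weight(s).
#' @export
wls_weight <- function(D_hat, k, n_t, eps = 1e-6) {
  D_hat <- pmax(D_hat, eps)
  e <- exp(-k * D_hat)
  n_t * e / (1 - e)
}

#' Pairwise distance matrix from k-mer tables
#'
#' Computes [shared_counts()] for every pair and converts them to distances
#' with [kmer_distance()] (or, with `backsub = TRUE`, the back-substitution
#' corrected inversion). The shared/total counts are kept alongside the
#' matrix because the tree fit needs per-pair `n_t` for its weights.
#'
#' @param tables list of `aaf_kmer_table` objects with a common `k`.
#' @param backsub apply the back-substitution correction.
#' @param model substitution model used when `backsub = TRUE`.
#' @return object of class `aaf_dist`: list with `taxa`, `D` (symmetric
#'   distance matrix), `ns`, `nt` (matrices of pair counts), `k`,
#'   `filtered`.
#' @export
kmer_distance_matrix <- function(tables, backsub = FALSE,
                                 model = substitution_model()) {
  n <- length(tables)
  if (n < 3) stop("need at least 3 taxa")
  ks <- vapply(tables, `[[`, integer(1), "k")
  if (length(unique(ks)) != 1L) stop("tables disagree on k")
  k <- ks[1]
  taxa <- vapply(tables, `[[`, character(1), "taxon_id")
  if (anyDuplicated(taxa)) stop("duplicate taxon ids")
  D <- ns <- nt <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sc <- shared_counts(tables[[i]], tables[[j]])
      ns[i, j] <- ns[j, i] <- sc$n_s
      nt[i, j] <- nt[j, i] <- sc$n_t
      d <- if (backsub && sc$n_s > 0) {
        kmer_distance_backsub(sc$n_s / sc$n_t, k, model)
      } else {
        kmer_distance(sc$n_s, sc$n_t, k)
      }
      D[i, j] <- D[j, i] <- d
    }
  }
  filtered <- any(vapply(tables, function(tb) isTRUE(tb$filtered), logical(1)))
  structure(list(taxa = taxa, D = D, ns = ns, nt = nt, k = k,
                 filtered = filtered),
            class = "aaf_dist")
}

#' Assemble an `aaf_dist` from precomputed matrices
#'
#' Used by the bootstrap machinery, which recomputes counts from resampled
#' tables, and by callers with externally computed counts.
#'
#' @param D symmetric distance matrix with dimnames.
#' @param ns,nt matrices of shared/total counts (same dimnames).
#' @param k k-mer length.
#' @param filtered singleton-filter flag carried for provenance.
#' @return `aaf_dist` object.
#' @export
aaf_dist <- function(D, ns, nt, k, filtered = FALSE) {
  stopifnot(is.matrix(D), !is.null(rownames(D)))
  structure(list(taxa = rownames(D), D = D, ns = ns, nt = nt, k = k,
                 filtered = filtered),
            class = "aaf_dist")
}

#' @export
print.aaf_dist <- function(x, ...) {
  cat("aaf_dist: ", length(x$taxa), " taxa, k = ", x$k,
      if (x$filtered) ", singleton-filtered", "\n", sep = "")
  print(round(x$D, 6))
  invisible(x)
}

#' Write a distance matrix in PHYLIP square format
#'
#' Tab-separated variant, plus an optional sidecar TSV with per-pair shared
#' and total k-mer counts.
#'
#' @param M an `aaf_dist`.
#' @param file output path.
#' @param sidecar optional path for the per-pair `n_s`/`n_t` table.
#' @export
write_phylip <- function(M, file, sidecar = NULL) {
  stopifnot(inherits(M, "aaf_dist"))
  con <- file(file, "w")
  on.exit(close(con))
  writeLines(sprintf("%d", length(M$taxa)), con)
  for (i in seq_along(M$taxa)) {
    writeLines(paste(c(M$taxa[i], sprintf("%.8f", M$D[i, ])), collapse = "\t"),
               con)
  }
  if (!is.null(sidecar)) {
    pr <- which(upper.tri(M$D), arr.ind = TRUE)
    df <- data.frame(taxon_a = M$taxa[pr[, 1]], taxon_b = M$taxa[pr[, 2]],
                     n_s = M$ns[pr], n_t = M$nt[pr])
    write.table(df, sidecar, sep = "\t", quote = FALSE, row.names = FALSE)
  }
  invisible(file)
}
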