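#' Resample reads with replacement
#'
#' First bootstrap stage: for every taxon, draw as many reads as it has,
#' with replacement. Captures the sampling variability of incomplete
#' coverage and sequencing error.
#'
#' @param reads_per_taxon named list of character vectors of reads.
#' @return list of the same shape with resampled reads.
#' @export
resample_reads <- function(reads_per_taxon) {
  lapply(reads_per_taxon, function(rd) {
    if (!length(rd)) stop("taxon with no reads; parametric mode handles assemblies")
    rd[sample.int(length(rd), length(rd), replace = TRUE)]
  })
}

#' Resample 1/k of the rows of a presence/absence table
#'
#' Second bootstrap stage: draw `round(M/k)` of the `M` k-mers with
#' replacement and recompute shared/total counts from the reduced table.
#' Taking only one row in `k` accounts for the non-independence of
#' overlapping k-mers (each genome position is covered by up to `k`
#' k-mers) — a block-bootstrap argument; the distance estimator only uses
#' the ratio `n_s/n_t`, which is scale-free in the number of rows.
#'
#' @param merged result of [merge_kmer_tables()].
#' @param k k-mer length used for the 1/k thinning.
#' @return list with matrices `ns` and `nt` (pairwise shared and
#'   min-total counts computed from the resampled rows).
#' @export
resample_rows <- function(merged, k = merged$k) {
  M <- nrow(merged$presence)
  if (M < k) stop("fewer rows than k")
  idx <- sample.int(M, max(1L, round(M / k)), replace = TRUE)
  P <- merged$presence[idx, , drop = FALSE]
  ns <- crossprod(P)
  tot <- diag(ns)
  nt <- outer(tot, tot, pmin)
  list(ns = ns, nt = nt)
}

dist_from_counts <- function(ns, nt, k, filtered = FALSE) {
  taxa <- rownames(ns)
  D <- matrix(0, nrow(ns), ncol(ns), dimnames = dimnames(ns))
  pr <- which(upper.tri(D), arr.ind = TRUE)
  D[pr] <- suppressWarnings(kmer_distance(ns[pr], nt[pr], k))
  D[lower.tri(D)] <- t(D)[lower.tri(D)]
  aaf_dist(D, ns, nt, k, filtered)
}

counts_from_tables <- function(tables) {
  n <- length(tables)
  taxa <- vapply(tables, `[[`, character(1), "taxon_id")
  ns <- nt <- matrix(0, n, n, dimnames = list(taxa, taxa))
  for (i in seq_len(n - 1)) {
    for (j in (i + 1):n) {
      sc <- shared_counts(tables[[i]], tables[[j]])
      ns[i, j] <- ns[j, i] <- sc$n_s
      nt[i, j] <- nt[j, i] <- sc$n_t
    }
  }
  diag(ns) <- diag(nt) <- vapply(tables, `[[`, numeric(1), "n_distinct")
  list(ns = ns, nt = nt)
}

# Count, for each internal split of `ref`, how many trees in `trees`
# contain it.
support_counts <- function(ref, trees) {
  keys <- names(split_lengths(ref, internal_only = TRUE))
  counts <- setNames(integer(length(keys)), keys)
  for (tr in trees) {
    hit <- keys %in% names(split_lengths(tr, internal_only = TRUE))
    counts[hit] <- counts[hit] + 1L
  }
  counts
}

# Attach "stage2(stage1)" support labels to the internal nodes of ref.
annotate_support <- function(ref, s2, s1 = NULL) {
  ref <- ape::unroot(ref)
  et <- edge_tip_matrix(ref)
  labs <- sort(ref$tip.label)
  m <- et$m[, labs, drop = FALSE]
  ntip <- length(ref$tip.label)
  tree <- et$tree
  tree$node.label <- rep("", tree$Nnode)
  for (e in seq_len(nrow(m))) {
    child <- tree$edge[e, 2]
    if (child <= ntip) next
    side <- m[e, ]
    if (side[1]) side <- !side
    key <- paste(labs[side], collapse = "|")
    if (key %in% names(s2)) {
      lab <- as.character(s2[[key]])
      if (!is.null(s1) && key %in% names(s1))
        lab <- paste0(lab, "(", s1[[key]], ")")
      tree$node.label[child - ntip] <- lab
    }
  }
  tree
}

#' Two-stage nonparametric bootstrap from reads
#'
#' Stage 1 resamples each taxon's reads with replacement and reruns the
#' whole pipeline (count, distances, tree), capturing sampling
#' variability. Stage 2 additionally thins each stage-1 presence/absence
#' table to 1/k of its rows ([resample_rows()]), adding evolutionary
#' variability. Support for each internal bipartition of the reference
#' tree is the number of replicate trees containing it.
#'
#' @param reads_per_taxon named list of character vectors of reads.
#' @param k k-mer length.
#' @param filter_singletons singleton filtering flag for counting.
#' @param B number of bootstrap replicates.
#' @param seed optional RNG seed for reproducibility.
#' @param ref_tree optional precomputed reference tree (fitted from the
#'   original reads if omitted).
#' @return list with `tree` (reference tree annotated "stage2(stage1)"),
#'   `support` (data.frame of per-split counts) and the replicate trees.
#' @export
nonparametric_bootstrap <- function(reads_per_taxon, k,
                                    filter_singletons = FALSE, B = 100,
                                    seed = NULL, ref_tree = NULL) {
  stopifnot(B >= 1)
  if (!is.null(seed)) set.seed(seed)
  count_all <- function(reads) {
    mapply(function(rd, nm) count_kmers(rd, k, nm, filter_singletons),
           reads, names(reads), SIMPLIFY = FALSE)
  }
  if (is.null(ref_tree)) {
    ref_tree <- fit_tree(kmer_distance_matrix(count_all(reads_per_taxon)))
  }
  trees1 <- trees2 <- vector("list", B)
  for (b in seq_len(B)) {
    tables <- count_all(resample_reads(reads_per_taxon))
    cc <- counts_from_tables(tables)
    trees1[[b]] <- fit_tree(dist_from_counts(cc$ns, cc$nt, k, filter_singletons))
    rr <- resample_rows(merge_kmer_tables(tables), k)
    trees2[[b]] <- fit_tree(dist_from_counts(rr$ns, rr$nt, k, filter_singletons))
  }
  s1 <- support_counts(ref_tree, trees1)
  s2 <- support_counts(ref_tree, trees2)
  list(tree = annotate_support(ref_tree, s2, s1),
       support = data.frame(split = names(s1), stage1 = as.integer(s1),
                            stage2 = as.integer(s2), B = B),
       stage1_trees = trees1, stage2_trees = trees2)
}

#' Stage-1 (sampling) standard deviation of a pairwise distance
#'
#' The sampling variance of `log(n_s*/n_t*)` augmented for the
#' non-independence of overlapping k-mers within reads: the total-count
#' term is inflated by `(1 + (r - k)/L)` on the retention part and
#' `(1 + w)` on the false-k-mer part, with
#' `w = sum_{i=1}^{k-1} 2i / (k (r - k + 1)) * max(0, r - 2k + i + 1)`.
#' The returned standard deviation (on the distance scale) is multiplied
#' by `sd_inflation` (default 2), a deliberate conservatism: the closed
#' form can err by up to ~50% in either direction.
#'
#' @param rates an [observed_true_ratios()] result.
#' @param n_s observed shared k-mer count of the pair.
#' @param sd_inflation multiplier on the standard deviation.
#' @return standard deviation of the pair's distance estimate.
#' @export
sampling_sd <- function(rates, n_s, sd_inflation = 2) {
  stopifnot(inherits(rates, "aaf_sampling_rates"), n_s > 0)
  p <- rates$params
  k <- p$k; r <- p$r; L <- p$L
  q_s <- rates$q_s; q_t <- rates$q_t
  w <- kmer_overlap_w(k, r)
  t1 <- log1p((q_s * (1 - q_s) + rates$p_sa) / (q_s + rates$p_sa)^2 / n_s)
  t2 <- log1p((q_t * (1 - q_t) * (1 + (r - k) / L) + rates$p_ta * (1 + w)) /
                (q_t + rates$p_ta)^2 / n_s)
  sd_inflation * sqrt((t1 + t2) / k^2)
}

#' Overlap weight used by the stage-1 sampling variance
#'
#' `w = sum_{i=1}^{k-1} 2i / (k (r - k + 1)) * max(0, r - 2k + i + 1)`;
#' zero when reads are exactly one k-mer long (r equal to k).
#'
#' @param k k-mer length.
#' @param r read length.
#' @return the overlap weight.
#' @export
kmer_overlap_w <- function(k, r) {
  i <- seq_len(k - 1)
  sum(2 * i / (k * (r - k + 1)) * pmax(0, r - 2 * k + i + 1))
}

#' Stage-2 (evolutionary) variance of a pairwise distance
#'
#' Variance of the distance estimate caused by the randomness of the
#' mutation process itself, with the covariance of overlapping k-mers:
#' `(1/(k^2 n_t)) [(e^{kD} - 1) + 2 sum_{i=1}^{k-1} (e^{iD} - 1)]`. At
#' `k = 1` this reduces to `(e^D - 1)/n_t`, the inverse of the
#' [wls_weight()] variance.
#'
#' @param k k-mer length.
#' @param n_t total distinct k-mers of the pair.
#' @param D pairwise distance (vectorized).
#' @return variance(s) on the distance scale.
#' @export
evolutionary_variance <- function(k, n_t, D) {
  s <- vapply(D, function(d)
    if (k > 1) sum(exp(seq_len(k - 1) * d) - 1) else 0, numeric(1))
  ((exp(k * D) - 1) + 2 * s) / (k^2 * n_t)
}

#' Covariance of pairwise distances induced by shared branches
#'
#' Two pairwise distances that share part of their paths on the tree
#' covary: the covariance is scaled by the shared-path length (in
#' distance units), with the diagonal anchored at the
#' [evolutionary_variance()] of each pair. Off-diagonal entries use the
#' geometric mean of the two pairs' variance-per-unit-path-length. The
#' result is projected onto the nearest positive semi-definite matrix
#' (eigenvalue clipping) if numerical noise pushes it outside.
#'
#' @param tree fitted reference `phylo` tree.
#' @param M `aaf_dist` with the pair `n_t` counts.
#' @return covariance matrix over unordered taxon pairs, with attribute
#'   `"pairs"` (2-column matrix of taxon indices into `M$taxa`).
#' @export
shared_branch_covariance <- function(tree, M) {
  et <- edge_tip_matrix(ape::unroot(tree))
  m <- et$m[, M$taxa, drop = FALSE]
  pr <- combn(length(M$taxa), 2)
  A <- 1 * t(m[, pr[1, ], drop = FALSE] != m[, pr[2, ], drop = FALSE])
  len <- et$tree$edge.length
  S <- A %*% (len * t(A))          # shared path lengths; diag = patristic D
  Dpath <- pmax(diag(S), 1e-12)
  v <- evolutionary_variance(M$k, M$nt[t(pr)], Dpath)
  rate <- sqrt(v / Dpath)          # sd per unit shared path, squared below
  Sigma <- S * outer(rate, rate)
  ev <- eigen(Sigma, symmetric = TRUE)
  if (any(ev$values < -1e-10 * max(abs(ev$values)))) {
    message("covariance projected to nearest positive semi-definite matrix")
    vals <- pmax(ev$values, 0)
    Sigma <- ev$vectors %*% (vals * t(ev$vectors))
  }
  attr(Sigma, "pairs") <- t(pr)
  Sigma
}

#' Two-stage parametric bootstrap on the distance matrix
#'
#' Operates on the distance matrix only (cost independent of genome
#' size). Stage 1 contaminates each pairwise distance with independent
#' zero-mean Gaussian noise whose standard deviation is [sampling_sd()]
#' (incomplete coverage + sequencing error, inflated for conservatism);
#' stage 2 adds correlated Gaussian noise with [evolutionary_variance()]
#' marginals and [shared_branch_covariance()] structure. Contaminated
#' distances are floored at zero and a tree is refitted per replicate.
#'
#' @param M `aaf_dist` from the original data.
#' @param tree fitted reference tree.
#' @param params_list named list of per-taxon [sampling_params()].
#' @param B replicates.
#' @param sd_inflation stage-1 standard-deviation multiplier.
#' @param seed optional RNG seed.
#' @return same shape as [nonparametric_bootstrap()].
#' @export
parametric_bootstrap <- function(M, tree, params_list, B = 100,
                                 sd_inflation = 2, seed = NULL) {
  stopifnot(inherits(M, "aaf_dist"), B >= 1)
  if (!is.null(seed)) set.seed(seed)
  pr <- combn(length(M$taxa), 2)
  idx <- cbind(pr[1, ], pr[2, ])
  sd1 <- vapply(seq_len(ncol(pr)), function(p) {
    i <- pr[1, p]; j <- pr[2, p]
    lower <- if (M$nt[i, i] <= M$nt[j, j]) i else j
    rates <- observed_true_ratios(params_list[[M$taxa[lower]]], d = M$D[i, j])
    # the variance formula is written in terms of the *true* shared count;
    # recover it from the observed one via the predicted observed/true ratio
    ns_true <- max(M$ns[i, j] / max(rates$p_s, 1e-12), 1)
    sampling_sd(rates, ns_true, sd_inflation)
  }, numeric(1))
  Sigma <- shared_branch_covariance(tree, M)
  R <- chol(Sigma + diag(1e-14, nrow(Sigma)))

  make_dist <- function(dvec) {
    D <- matrix(0, length(M$taxa), length(M$taxa),
                dimnames = list(M$taxa, M$taxa))
    D[idx] <- pmax(dvec, 0)
    D[lower.tri(D)] <- t(D)[lower.tri(D)]
    aaf_dist(D, M$ns, M$nt, M$k, M$filtered)
  }
  d0 <- M$D[idx]
  trees1 <- trees2 <- vector("list", B)
  for (b in seq_len(B)) {
    d1 <- d0 + rnorm(length(d0), 0, sd1)
    trees1[[b]] <- fit_tree(make_dist(d1))
    d2 <- d1 + drop(t(R) %*% rnorm(length(d0)))
    trees2[[b]] <- fit_tree(make_dist(d2))
  }
  s1 <- support_counts(tree, trees1)
  s2 <- support_counts(tree, trees2)
  list(tree = annotate_support(tree, s2, s1),
       support = data.frame(split = names(s1), stage1 = as.integer(s1),
                            stage2 = as.integer(s2), B = B),
       stage1_trees = trees1, stage2_trees = trees2)
}
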