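#' @importFrom stats lm.wfit
NULL

# Edge/tip incidence of a tree: for every edge, which tips lie below the
# child node. Returns the postorder-reordered tree together with the
# (nedge x ntip) logical matrix so edge indices line up.
edge_tip_matrix <- function(tree) {
  tree <- ape::reorder.phylo(tree, "postorder")
  ntip <- length(tree$tip.label)
  nn <- ntip + tree$Nnode
  below <- matrix(FALSE, nn, ntip)
  below[cbind(seq_len(ntip), seq_len(ntip))] <- TRUE
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]
    below[par, ] <- below[par, ] | below[tree$edge[e, 2], ]
  }
  m <- below[tree$edge[, 2], , drop = FALSE]
  colnames(m) <- tree$tip.label
  list(tree = tree, m = m)
}

# Weighted non-negative least squares by naive active-set: solve, clamp
# negative coefficients to zero, re-solve on the free set.
nnls_solve <- function(A, y, w) {
  p <- ncol(A)
  free <- rep(TRUE, p)
  b <- numeric(p)
  repeat {
    fit <- lm.wfit(A[, free, drop = FALSE], y, w)
    bf <- fit$coefficients
    bf[is.na(bf)] <- 0
    if (all(bf >= -1e-10)) {
      b[free] <- pmax(bf, 0)
      break
    }
    idx <- which(free)
    free[idx[bf < -1e-10]] <- FALSE
    if (!any(free)) break
  }
  b
}

# Fit non-negative branch lengths to a fixed topology by weighted least
# squares with iteratively reweighted inverse-variance weights.
fit_lengths <- function(topo, M, max_iter = 20, rtol = 1e-8) {
  et <- edge_tip_matrix(topo)
  m <- et$m[, M$taxa, drop = FALSE]
  pr <- combn(length(M$taxa), 2)
  A <- 1 * t(m[, pr[1, ], drop = FALSE] != m[, pr[2, ], drop = FALSE])
  idx <- cbind(pr[1, ], pr[2, ])
  d <- M$D[idx]
  nt <- M$nt[idx]
  Dhat <- d
  obj <- Inf
  b <- numeric(ncol(A))
  for (it in seq_len(max_iter)) {
    w <- wls_weight(Dhat, M$k, nt)
    b <- nnls_solve(A, d, w)
    Dhat <- drop(A %*% b)
    obj_new <- sum(wls_weight(Dhat, M$k, nt) * (d - Dhat)^2)
    if (is.finite(obj) && abs(obj - obj_new) <= rtol * max(1, obj_new)) {
      obj <- obj_new
      break
    }
    obj <- obj_new
  }
  tree <- et$tree
  tree$edge.length <- b
  list(tree = tree, objective = obj)
}

star_tree3 <- function(M) {
  d <- M$D
  b <- c((d[1, 2] + d[1, 3] - d[2, 3]) / 2,
         (d[1, 2] + d[2, 3] - d[1, 3]) / 2,
         (d[1, 3] + d[2, 3] - d[1, 2]) / 2)
  tr <- list(edge = cbind(rep(4L, 3), 1:3),
             edge.length = pmax(b, 0),
             tip.label = M$taxa, Nnode = 1L)
  class(tr) <- "phylo"
  tr
}

#' Fit an unrooted tree by weighted least squares
#'
#' Topology search: neighbour-joining starting tree, then
#' nearest-neighbour-interchange hill climbing under the weighted
#' least-squares objective. At every evaluated topology, non-negative
#' branch lengths are fitted with inverse-variance weights
#' ([wls_weight()]) recomputed from the current fitted distances
#' (iterated to convergence). Ties keep the incumbent topology, and taxa
#' are processed in label order internally, so the result does not depend
#' on input order. The returned tree is locally optimal: no single NNI
#' move improves the objective.
#'
#' @param M an `aaf_dist` distance matrix.
#' @return an unrooted `phylo` tree with non-negative branch lengths.
#' @export
fit_tree <- function(M) {
  stopifnot(inherits(M, "aaf_dist"))
  if (!all(is.finite(M$D)))
    stop("non-finite distances; fix degenerate pairs before fitting")
  ord <- order(M$taxa)
  M <- aaf_dist(M$D[ord, ord, drop = FALSE], M$ns[ord, ord, drop = FALSE],
                M$nt[ord, ord, drop = FALSE], M$k, M$filtered)
  n <- length(M$taxa)
  if (n < 3) stop("need at least 3 taxa")
  if (n == 3) return(star_tree3(M))

  topo <- ape::unroot(ape::nj(M$D))
  cur <- fit_lengths(topo, M)
  repeat {
    nbrs <- phangorn::nni(cur$tree)
    # screen candidates with a cheap partially-reweighted fit, then refit
    # the best one fully before deciding
    objs <- vapply(nbrs, function(nb)
      fit_lengths(nb, M, max_iter = 3)$objective, numeric(1))
    best <- which.min(objs)
    eps <- 1e-12 * max(1, cur$objective)
    if (objs[best] < cur$objective - eps) {
      cand <- fit_lengths(nbrs[[best]], M)
      if (cand$objective < cur$objective - eps) {
        cur <- cand
        next
      }
    }
    break
  }
  cur$tree
}

#' Fit branch lengths on a fixed topology
#'
#' Non-negative weighted least-squares branch lengths for a given
#' (unrooted) topology, with the same iterated inverse-variance weighting
#' as [fit_tree()] but no topology search.
#'
#' @param topology `phylo` tree spanning the taxa of `M` (branch lengths,
#'   if any, are ignored).
#' @param M an `aaf_dist`.
#' @return the topology with fitted branch lengths.
#' @export
fit_branch_lengths <- function(topology, M) {
  stopifnot(inherits(M, "aaf_dist"))
  if (!setequal(topology$tip.label, M$taxa)) stop("taxon set mismatch")
  fit_lengths(topology, M)$tree
}

#' Weighted least-squares objective of a tree against a distance matrix
#'
#' `sum over pairs of w(k D_hat_ij) (D_ij - D_hat_ij)^2`, with patristic
#' distances `D_hat` read off the tree and inverse-variance weights from
#' [wls_weight()] using each pair's `n_t`.
#'
#' @param tree `phylo` tree spanning the taxa of `M`.
#' @param M an `aaf_dist`.
#' @return the weighted sum of squares.
#' @export
wls_objective <- function(tree, M) {
  stopifnot(inherits(M, "aaf_dist"))
  if (!setequal(tree$tip.label, M$taxa)) stop("taxon set mismatch")
  Dhat <- ape::cophenetic.phylo(tree)[M$taxa, M$taxa]
  pr <- which(upper.tri(M$D), arr.ind = TRUE)
  dh <- Dhat[pr]
  sum(wls_weight(dh, M$k, M$nt[pr]) * (M$D[pr] - dh)^2)
}

#' Shorten terminal branches by per-taxon tip corrections
#'
#' Applies [tip_correction()] (or [average_tip_correction()]) amounts to a
#' fitted tree: each terminal branch is reduced by its taxon's correction,
#' floored at zero (floor events produce a warning). Topology and internal
#' branch lengths are untouched; corrections must only be applied after
#' the topology has been fitted.
#'
#' @param tree fitted `phylo` tree.
#' @param corrections named numeric vector of non-negative per-taxon
#'   corrections (a single unnamed value is recycled to all tips).
#' @return the corrected tree.
#' @export
trim_tips <- function(tree, corrections) {
  stopifnot(inherits(tree, "phylo"), all(corrections >= 0))
  if (is.null(names(corrections))) {
    if (length(corrections) != 1)
      stop("corrections must be named or a single value")
    corrections <- setNames(rep(corrections, length(tree$tip.label)),
                            tree$tip.label)
  }
  unknown <- setdiff(names(corrections), tree$tip.label)
  if (length(unknown))
    stop("unknown taxa in corrections: ", paste(unknown, collapse = ", "))
  tipedge <- match(seq_along(tree$tip.label), tree$edge[, 2])
  for (taxon in names(corrections)) {
    i <- tipedge[match(taxon, tree$tip.label)]
    newlen <- tree$edge.length[i] - corrections[[taxon]]
    if (newlen < 0) {
      warning("tip branch of '", taxon, "' shorter than its correction; floored at 0")
      newlen <- 0
    }
    tree$edge.length[i] <- newlen
  }
  tree
}

# Canonical bipartition keys of an unrooted tree. Each edge's split is
# represented by the tip subset NOT containing the alphabetically first
# taxon, as a "|"-collapsed sorted label string. Returns a named numeric
# vector of branch lengths keyed by split; for rooted input the two root
# edges describing the same split are merged by summing.
split_lengths <- function(tree, internal_only = FALSE) {
  tree <- ape::unroot(tree)
  et <- edge_tip_matrix(tree)
  labs <- sort(tree$tip.label)
  m <- et$m[, labs, drop = FALSE]
  n <- length(labs)
  keys <- character(nrow(m))
  keep <- logical(nrow(m))
  for (e in seq_len(nrow(m))) {
    side <- m[e, ]
    if (side[1]) side <- !side
    sz <- sum(side)
    keys[e] <- paste(labs[side], collapse = "|")
    keep[e] <- !internal_only || (sz >= 2 && sz <= n - 2)
  }
  len <- et$tree$edge.length
  if (is.null(len)) len <- rep(NA_real_, nrow(m))
  tapply(len[keep], keys[keep], sum)
}

#' Branch score distance between two trees
#'
#' Matches branches between the trees by the bipartition of taxa they
#' induce; matched branches contribute the squared difference of their
#' lengths, unmatched branches their full squared length. By default the
#' square root of the sum is returned (the convention of the classical
#' tree-distance programs); `take_sqrt = FALSE` gives the raw sum of
#' squared differences.
#'
#' @param t1,t2 `phylo` trees over the same taxa.
#' @param take_sqrt return the square root of the sum.
#' @return non-negative branch score distance.
#' @export
branch_score_distance <- function(t1, t2, take_sqrt = TRUE) {
  if (!setequal(t1$tip.label, t2$tip.label)) stop("taxon set mismatch")
  l1 <- split_lengths(t1)
  l2 <- split_lengths(t2)
  keys <- union(names(l1), names(l2))
  v1 <- ifelse(keys %in% names(l1), l1[keys], 0)
  v2 <- ifelse(keys %in% names(l2), l2[keys], 0)
  ss <- sum((v1 - v2)^2)
  if (take_sqrt) sqrt(ss) else ss
}

#' Topological mistakes of a tree relative to a reference
#'
#' The number of internal bipartitions of `t1` absent from `t2` (half the
#' Robinson-Foulds distance for binary trees); 0 iff the unrooted
#' topologies agree.
#'
#' @param t1 tree under evaluation.
#' @param t2 reference tree (same taxa).
#' @return integer count.
#' @export
topological_mistakes <- function(t1, t2) {
  if (!setequal(t1$tip.label, t2$tip.label)) stop("taxon set mismatch")
  k1 <- names(split_lengths(t1, internal_only = TRUE))
  k2 <- names(split_lengths(t2, internal_only = TRUE))
  sum(!(k1 %in% k2))
}
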