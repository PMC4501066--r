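#' Parameters of the sequence-evolution simulator
#'
#' An HKY-type substitution process (transition bias `kappa`, base
#' frequencies from the GC content `u`) with indels: the combined
#' insertion+deletion event rate is `indel_fraction` of the total mutation
#' rate, split evenly between insertions and deletions, with lengths
#' uniform on `1:indel_max`. Inserted bases are drawn i.i.d. from the base
#' frequencies.
#'
#' @param kappa transition bias (rate multiplier for transitions).
#' @param indel_fraction combined indel event rate as a fraction of the
#'   substitution rate.
#' @param indel_max maximum indel length (lengths uniform on 1..indel_max).
#' @param u GC content of the stationary base frequencies.
#' @return object of class `aaf_evolution_params`.
#' @export
evolution_params <- function(kappa = 2, indel_fraction = 0.1, indel_max = 5,
                             u = 0.5) {
  stopifnot(kappa > 0, indel_fraction >= 0, indel_max >= 1, u > 0, u < 1)
  pi <- c(A = (1 - u) / 2, C = u / 2, G = u / 2, T = (1 - u) / 2)
  # per-base substitution target table: transition partner and the two
  # transversions, with HKY weights kappa*pi (transition) and pi
  ts_partner <- c(3L, 4L, 1L, 2L)  # A<->G, C<->T (1-based base index)
  tmat <- matrix(0L, 4, 3)
  pcum <- matrix(0, 4, 2)
  for (b in 1:4) {
    tg <- setdiff(1:4, b)
    w <- ifelse(tg == ts_partner[b], kappa, 1) * pi[tg]
    w <- w / sum(w)
    tmat[b, ] <- tg
    pcum[b, ] <- cumsum(w)[1:2]
  }
  structure(list(kappa = kappa, indel_fraction = indel_fraction,
                 indel_max = indel_max, u = u, pi = pi,
                 tmat = tmat, pcum = pcum),
            class = "aaf_evolution_params")
}

BASES <- c("A", "C", "G", "T")

seq_to_int <- function(s) {
  match(utf8ToInt(s), c(65L, 67L, 71L, 84L))
}

int_to_seq <- function(x) {
  intToUtf8(c(65L, 67L, 71L, 84L)[x])
}

#' Random i.i.d. genome
#'
#' @param g genome length in bp.
#' @param u GC content: P(G) = P(C) = u/2, P(A) = P(T) = (1-u)/2.
#' @return a single nucleotide string.
#' @export
random_genome <- function(g, u = 0.5) {
  stopifnot(g >= 1)
  pi <- c((1 - u) / 2, u / 2, u / 2, (1 - u) / 2)
  int_to_seq(sample.int(4L, g, replace = TRUE, prob = pi))
}

# Apply n_sub substitution events at uniform positions (multiple hits at a
# site compound sequentially).
apply_substitutions <- function(x, pos, params) {
  while (length(pos)) {
    first <- !duplicated(pos)
    p <- pos[first]
    cur <- x[p]
    r <- runif(length(p))
    idx <- 1L + (r > params$pcum[cur, 1]) + (r > params$pcum[cur, 2])
    x[p] <- params$tmat[cbind(cur, idx)]
    pos <- pos[!first]
  }
  x
}

# Deletions (keep-mask) and insertions (anchored before original
# coordinates) applied in one assembly pass.
apply_indels <- function(x, del_pos, del_len, ins_pos, ins_seqs) {
  g <- length(x)
  keep <- rep(TRUE, g)
  for (i in seq_along(del_pos)) {
    keep[del_pos[i]:min(g, del_pos[i] + del_len[i] - 1L)] <- FALSE
  }
  if (!length(ins_pos)) return(x[keep])
  o <- order(ins_pos)
  ins_pos <- ins_pos[o]
  ins_seqs <- ins_seqs[o]
  parts <- vector("list", 2L * length(ins_pos) + 1L)
  prev <- 1L
  for (i in seq_along(ins_pos)) {
    seg <- if (ins_pos[i] > prev) prev:(ins_pos[i] - 1L) else integer(0)
    parts[[2L * i - 1L]] <- x[seg][keep[seg]]
    parts[[2L * i]] <- ins_seqs[[i]]
    prev <- ins_pos[i]
  }
  seg <- prev:g
  parts[[2L * length(ins_pos) + 1L]] <- x[seg][keep[seg]]
  unlist(parts, use.names = FALSE)
}

# Evolve an integer-coded sequence along one branch of length d (expected
# mutation events per site, substitutions and indels combined).
evolve_branch <- function(x, d, params) {
  if (d < 0) stop("negative branch length")
  if (d == 0) return(x)
  g <- length(x)
  f <- params$indel_fraction
  n_sub <- rpois(1, g * d / (1 + f))
  n_ind <- rpois(1, g * d * f / (1 + f))
  if (n_sub > 0)
    x <- apply_substitutions(x, sample.int(g, n_sub, replace = TRUE), params)
  if (n_ind > 0) {
    is_ins <- runif(n_ind) < 0.5
    pos <- sample.int(length(x), n_ind, replace = TRUE)
    len <- sample.int(params$indel_max, n_ind, replace = TRUE)
    ins_seqs <- lapply(len[is_ins], function(l)
      sample.int(4L, l, replace = TRUE, prob = params$pi))
    x <- apply_indels(x, pos[!is_ins], len[!is_ins], pos[is_ins], ins_seqs)
  }
  if (length(x) < 1) stop("sequence vanished: branch too long for deletions")
  x
}

#' Evolve an ancestral sequence along a tree
#'
#' Recurses from the root to the tips, mutating the sequence along each
#' branch. Branch lengths are expected mutation events (substitutions plus
#' indel events) per site, the same scale on which [kmer_distance()]
#' estimates distances.
#'
#' @param ancestor ancestral nucleotide string (e.g. [random_genome()]).
#' @param tree rooted `phylo` object with branch lengths.
#' @param params an [evolution_params()].
#' @return named character vector of tip sequences.
#' @export
evolve_on_tree <- function(ancestor, tree, params = evolution_params()) {
  stopifnot(inherits(tree, "phylo"), !is.null(tree$edge.length))
  tree <- ape::reorder.phylo(tree, "cladewise")  # parents before children
  ntip <- length(tree$tip.label)
  root <- ntip + 1L
  seqs <- vector("list", ntip + tree$Nnode)
  seqs[[root]] <- seq_to_int(ancestor)
  for (e in seq_len(nrow(tree$edge))) {
    par <- tree$edge[e, 1]
    chl <- tree$edge[e, 2]
    seqs[[chl]] <- evolve_branch(seqs[[par]], tree$edge.length[e], params)
  }
  out <- vapply(seqs[seq_len(ntip)], int_to_seq, character(1))
  setNames(out, tree$tip.label)
}

#' Two sequences separated by a fixed distance
#'
#' Evolves the ancestor down both arms of a two-tip star with branch
#' lengths `d/2`, so the tip-to-tip distance is `d`.
#'
#' @param ancestor ancestral nucleotide string.
#' @param d total distance between the two tips.
#' @param params an [evolution_params()].
#' @return character vector of length 2 (`A`, `B`).
#' @export
pair_at_distance <- function(ancestor, d, params = evolution_params()) {
  stopifnot(d >= 0)
  x <- seq_to_int(ancestor)
  c(A = int_to_seq(evolve_branch(x, d / 2, params)),
    B = int_to_seq(evolve_branch(x, d / 2, params)))
}

#' Simulate shotgun reads with uniform placement and i.i.d. errors
#'
#' Read starts are uniform on the linear genome (so positions within a read
#' length of the ends receive slightly less coverage); each base is flipped
#' to one of the three alternatives uniformly with probability
#' `error_rate`.
#'
#' @param genome nucleotide string.
#' @param coverage fold coverage (expected total read bases = coverage x
#'   genome length).
#' @param read_length read length in bp.
#' @param error_rate per-base error probability.
#' @return character vector of reads.
#' @export
simulate_reads <- function(genome, coverage, read_length = 70,
                           error_rate = 0.01) {
  g <- nchar(genome)
  stopifnot(read_length <= g, coverage >= 0)
  n_reads <- round(coverage * g / read_length)
  if (n_reads == 0) return(character(0))
  starts <- sample.int(g - read_length + 1L, n_reads, replace = TRUE)
  reads <- substring(genome, starts, starts + read_length - 1L)
  if (error_rate > 0)
    reads <- cpp_add_read_errors(reads, error_rate)
  reads
}

#' Write sequences as FASTA
#'
#' @param seqs named character vector of sequences.
#' @param file output path.
#' @export
write_fasta <- function(seqs, file) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(seqs), file, format = "fasta")
  invisible(file)
}

#' Write reads as FASTQ with constant quality
#'
#' @param reads character vector of reads.
#' @param file output path.
#' @param id_prefix read name prefix.
#' @export
write_fastq <- function(reads, file, id_prefix = "read") {
  con <- file(file, "w")
  on.exit(close(con))
  qual <- vapply(nchar(reads), function(n)
    paste(rep("I", n), collapse = ""), character(1))
  writeLines(paste0("@", id_prefix, seq_along(reads), "\n", reads,
                    "\n+\n", qual), con)
  invisible(file)
}

#' Reference 12-taxon simulation topology
#'
#' A synthetic primate-like ultrametric tree (root-to-tip distance 0.1)
#' used by the package's validation experiments: nested ape-like clades
#' with internode lengths spanning 0.002--0.035, so recovery difficulty
#' ranges from easy to hard at realistic genome sizes.
#'
#' @return a rooted `phylo` object with 12 tips.
#' @export
aaf_demo_tree <- function() {
  ape::read.tree(text = paste0(
    "((((((((t1:0.008,t2:0.008):0.003,t3:0.011):0.002,t4:0.013):0.005,",
    "t5:0.018):0.014,((t6:0.012,t7:0.012):0.008,t8:0.02):0.012):0.028,",
    "(t9:0.025,t10:0.025):0.035):0.015,t11:0.075):0.025,t12:0.1);"))
}
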