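# Independent brute-force oracles used across the test files. Everything
# here is intentionally naive string/R-level code, kept apart from the
# implementation paths it checks.

revcomp_chr <- function(s) {
  vapply(s, function(x)
    paste(rev(strsplit(chartr("ACGTacgt", "TGCATGCA", x), "")[[1]]),
          collapse = ""), character(1), USE.NAMES = FALSE)
}

canonical_oracle <- function(s) {
  s <- toupper(s)
  pmin(s, toupper(revcomp_chr(s)))
}

# Tally canonical k-mers of a set of sequences window by window.
count_oracle <- function(seqs, k) {
  wins <- unlist(lapply(seqs, function(s) {
    n <- nchar(s)
    if (n < k) return(character(0))
    substring(s, 1:(n - k + 1), k:n)
  }))
  wins <- wins[!grepl("[^ACGTacgt]", wins)]
  if (!length(wins)) return(integer(0))
  tab <- table(canonical_oracle(wins))
  out <- as.integer(tab)
  names(out) <- names(tab)
  out[order(names(out))]
}

# A random test sequence with optional ambiguity codes and soft masking.
random_test_seq <- function(n, p_ambig = 0, p_lower = 0) {
  ch <- sample(c("A", "C", "G", "T"), n, replace = TRUE)
  if (p_ambig > 0) {
    i <- runif(n) < p_ambig
    ch[i] <- sample(c("N", "R", "Y"), sum(i), replace = TRUE)
  }
  if (p_lower > 0) {
    i <- runif(n) < p_lower
    ch[i] <- tolower(ch[i])
  }
  paste(ch, collapse = "")
}

# Shared path length between the tip pairs of a tree, via ape::nodepath.
shared_path_oracle <- function(tree, a1, b1, a2, b2) {
  edge_key <- function(path) {
    apply(cbind(path[-length(path)], path[-1]), 1, function(e)
      paste(sort(e), collapse = "-"))
  }
  tip <- function(lbl) match(lbl, tree$tip.label)
  p1 <- ape::nodepath(tree, tip(a1), tip(b1))
  p2 <- ape::nodepath(tree, tip(a2), tip(b2))
  k1 <- edge_key(p1)
  k2 <- edge_key(p2)
  common <- intersect(k1, k2)
  if (!length(common)) return(0)
  all_keys <- apply(tree$edge, 1, function(e) paste(sort(e), collapse = "-"))
  sum(tree$edge.length[match(common, all_keys)])
}

count_tables_for <- function(seqs, k, filter = FALSE) {
  mapply(function(s, nm) count_kmers(s, k, nm, filter_singletons = filter),
         seqs, names(seqs), SIMPLIFY = FALSE)
}
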