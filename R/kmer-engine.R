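#' Canonical form of a k-mer
#'
#' Returns the lexicographically smaller of each k-mer and its reverse
#' complement, after uppercasing. A window containing any non-ACGT symbol
#' (ambiguity codes, gaps) yields `NA`, which callers treat as "skip this
#' window".
#'
#' @param kmer character vector of equal-length nucleotide strings.
#' @return character vector of canonical k-mers; `NA` where the input
#'   contains a non-ACGT symbol.
#' @examples
#' canonical_kmer(c("ACG", "TTT", "acg"))
#' @export
canonical_kmer <- function(kmer) {
  kmer <- as.character(kmer)
  if (length(kmer) == 0L) return(character(0))
  k <- unique(nchar(kmer))
  if (length(k) != 1L)
    stop("all k-mers must have the same length")
  if (k < 2 || k > 26)
    stop("k must be between 2 and 26")
  codes <- cpp_encode_canonical(kmer, as.integer(k))
  out <- rep(NA_character_, length(kmer))
  ok <- !is.na(codes)
  out[ok] <- cpp_decode_kmers(codes[ok], as.integer(k))
  out
}

#' Count canonical k-mers of one taxon
#'
#' Streams every length-`k` window of the input sequences, canonicalizes it
#' (lexicographic minimum of the window and its reverse complement) and
#' tallies copy numbers. Windows containing a non-ACGT character are skipped;
#' soft-masked (lowercase) bases are used. With `filter_singletons = TRUE`,
#' k-mers seen exactly once are dropped after counting — the standard guard
#' against k-mers created by sequencing errors in read data.
#'
#' @param sequences character vector of nucleotide sequences (e.g. reads or
#'   assembled contigs), or a `Biostrings::DNAStringSet`.
#' @param k k-mer length (integer, 2--26).
#' @param taxon_id name of the taxon the sequences belong to.
#' @param filter_singletons drop k-mers with copy number 1 after counting.
#' @return an object of class `aaf_kmer_table`: a list with elements
#'   `taxon_id`, `k`, `kmers` (sorted numeric 2-bit codes), `counts`
#'   (integer copy numbers), `n_distinct`, `n_windows` (total valid windows
#'   seen, before filtering), and `filtered`.
#' @seealso [shared_counts()], [kmer_spectrum()], [kmer_counts()]
#' @examples
#' tab <- count_kmers("ACGTACGT", k = 3, taxon_id = "toy")
#' kmer_counts(tab)
#' @export
count_kmers <- function(sequences, k, taxon_id = "taxon",
                        filter_singletons = FALSE) {
  if (inherits(sequences, "XStringSet"))
    sequences <- as.character(sequences)
  sequences <- as.character(sequences)
  k <- as.integer(k)
  if (length(sequences) == 0L || all(!nzchar(sequences))) {
    warning("empty input for taxon '", taxon_id, "': empty k-mer table")
    res <- list(kmers = numeric(0), counts = integer(0), n_windows = 0)
  } else {
    res <- cpp_count_kmers(sequences, k)
  }
  keep <- if (filter_singletons) res$counts >= 2L else rep(TRUE, length(res$counts))
  structure(
    list(taxon_id = taxon_id,
         k = k,
         kmers = res$kmers[keep],
         counts = res$counts[keep],
         n_distinct = sum(keep),
         n_windows = res$n_windows,
         filtered = filter_singletons),
    class = "aaf_kmer_table")
}

#' @export
print.aaf_kmer_table <- function(x, ...) {
  cat("aaf_kmer_table: taxon '", x$taxon_id, "', k = ", x$k, ", ",
      x$n_distinct, " distinct canonical k-mers",
      if (x$filtered) " (singletons filtered)", "\n", sep = "")
  invisible(x)
}

#' Named copy-number vector of a k-mer table
#'
#' Decodes the stored 2-bit codes back to strings. Intended for inspection
#' and testing; the pipeline itself works on the packed codes.
#'
#' @param table an `aaf_kmer_table`.
#' @return named integer vector: canonical k-mer string -> copy number,
#'   sorted lexicographically.
#' @export
kmer_counts <- function(table) {
  stopifnot(inherits(table, "aaf_kmer_table"))
  setNames(table$counts, cpp_decode_kmers(table$kmers, table$k))
}

#' Shared and total distinct k-mers of a taxon pair
#'
#' The sufficient statistic for the pairwise distance: `n_s` is the size of
#' the presence/absence intersection of the two tables (copy numbers are
#' ignored) and `n_t` is the smaller of the two distinct-k-mer totals. Using
#' the smaller total compensates for the asymmetric k-mer loss caused by
#' deletions.
#'
#' @param a,b `aaf_kmer_table` objects with equal `k`.
#' @return list with `taxon_a`, `taxon_b`, `n_s`, `n_t`.
#' @export
shared_counts <- function(a, b) {
  stopifnot(inherits(a, "aaf_kmer_table"), inherits(b, "aaf_kmer_table"))
  if (a$k != b$k)
    stop("k mismatch: ", a$k, " vs ", b$k)
  list(taxon_a = a$taxon_id, taxon_b = b$taxon_id,
       n_s = cpp_intersect_size(a$kmers, b$kmers),
       n_t = min(a$n_distinct, b$n_distinct))
}

#' Copy-number spectrum of a k-mer table
#'
#' Fraction of distinct k-mers occurring exactly `j` times in the genome
#' (`j >= 1`, total copy number). This empirical spectrum drives the
#' homoplasy prediction for real (non-random) genomes. Filtering truncates
#' the spectrum at 2, so filtered tables are rejected.
#'
#' @param table an unfiltered `aaf_kmer_table`.
#' @return object of class `aaf_spectrum`: list with `k` and `q`, a
#'   probability vector with `q[j]` the fraction of distinct k-mers of copy
#'   number `j`.
#' @export
kmer_spectrum <- function(table) {
  stopifnot(inherits(table, "aaf_kmer_table"))
  if (isTRUE(table$filtered))
    stop("spectrum requires an unfiltered table; re-count without singleton filtering")
  if (table$n_distinct == 0L)
    stop("empty k-mer table")
  q <- tabulate(table$counts) / table$n_distinct
  structure(list(k = table$k, q = q), class = "aaf_spectrum")
}

#' Read per-taxon sequence files
#'
#' Reads one or more FASTA or FASTQ files (plain or gzipped) belonging to a
#' single taxon and returns their sequences as a character vector. Multiple
#' files (e.g. several sequencing runs) are concatenated; results do not
#' depend on file order.
#'
#' @param files character vector of file paths.
#' @param format `"auto"` (by extension), `"fasta"` or `"fastq"`.
#' @return character vector of sequences.
#' @export
read_taxon_sequences <- function(files, format = c("auto", "fasta", "fastq")) {
  format <- match.arg(format)
  out <- lapply(files, function(f) {
    fmt <- format
    if (fmt == "auto") {
      fmt <- if (grepl("\\.(fq|fastq)(\\.gz)?$", f, ignore.case = TRUE))
        "fastq" else "fasta"
    }
    as.character(Biostrings::readDNAStringSet(f, format = fmt))
  })
  unname(unlist(out))
}

#' Merge k-mer tables into a presence/absence matrix
#'
#' @param tables list of `aaf_kmer_table` objects with a common `k`.
#' @return list with `kmers` (sorted numeric codes of the union) and
#'   `presence`, a 0/1 integer matrix (rows = k-mers, columns = taxa).
#' @export
merge_kmer_tables <- function(tables) {
  ks <- vapply(tables, `[[`, integer(1), "k")
  if (length(unique(ks)) != 1L) stop("tables disagree on k")
  taxa <- unname(vapply(tables, `[[`, character(1), "taxon_id"))
  if (anyDuplicated(taxa)) stop("duplicate taxon ids")
  union_codes <- sort(unique(unlist(lapply(tables, `[[`, "kmers"))))
  presence <- vapply(tables, function(tb)
    as.integer(union_codes %in% tb$kmers), integer(length(union_codes)))
  if (is.null(dim(presence)))
    presence <- matrix(presence, ncol = length(tables))
  colnames(presence) <- taxa
  list(kmers = union_codes, k = ks[1], presence = presence)
}

#' Write a merged presence/absence table as TSV
#'
#' First column is the canonical k-mer (lexicographically sorted), followed
#' by one 0/1 column per taxon.
#'
#' @param merged result of [merge_kmer_tables()].
#' @param file output path.
#' @export
write_kmer_table <- function(merged, file) {
  df <- data.frame(kmer = cpp_decode_kmers(merged$kmers, merged$k),
                   merged$presence, check.names = FALSE)
  write.table(df, file, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(file)
}
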