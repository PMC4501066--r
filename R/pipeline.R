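#' Run the full count-to-tree pipeline
#'
#' Orchestrates one reproducible run: read per-taxon FASTA/FASTQ, count
#' canonical k-mers (optionally filtering singletons), compute the
#' pairwise distance matrix, fit the weighted least-squares tree, apply
#' tip corrections if per-taxon sequencing parameters are supplied, and
#' optionally bootstrap. All artifacts are written under `output_dir`.
#'
#' The configuration is a list (or a YAML file with the same shape):
#' \describe{
#'   \item{taxa}{named list; each element either a character vector of
#'     files, or a list with `files` and optional `coverage`,
#'     `read_length`, `error_rate`.}
#'   \item{k}{k-mer length (required).}
#'   \item{filter}{singleton filtering; if omitted, on when every taxon
#'     with known coverage has coverage >= 5, off otherwise (a warning
#'     reports the decision).}
#'   \item{backsub}{apply the back-substitution corrected inversion
#'     (default `FALSE`).}
#'   \item{bootstrap}{optional list with `mode`
#'     (`"nonparametric"`/`"parametric"`), `B`, `seed`.}
#'   \item{output_dir}{where to write artifacts (default `"aaf_run"`).}
#'   \item{seed}{RNG seed for the run.}
#'   \item{write_table}{write the merged presence/absence TSV (can be
#'     large; default `FALSE`).}
#' }
#'
#' @param config list or path to a YAML file.
#' @return invisibly, a list with the k-mer tables, distance matrix,
#'   fitted/corrected/annotated trees and output paths.
#' @export
run_pipeline <- function(config) {
  if (is.character(config)) config <- yaml::read_yaml(config)
  stopifnot(is.list(config), !is.null(config$taxa), !is.null(config$k))
  k <- as.integer(config$k)
  out <- config$output_dir %||% "aaf_run"
  dir.create(out, showWarnings = FALSE, recursive = TRUE)
  if (!is.null(config$seed)) set.seed(config$seed)

  taxa_cfg <- lapply(config$taxa, function(tx)
    if (is.list(tx)) tx else list(files = tx))
  taxa <- names(taxa_cfg)
  if (is.null(taxa) || anyDuplicated(taxa))
    stop("config$taxa must be a uniquely named list")

  coverages <- vapply(taxa_cfg, function(tx)
    if (is.null(tx$coverage)) NA_real_ else tx$coverage, numeric(1))
  filter <- config$filter
  if (is.null(filter)) {
    filter <- length(coverages) > 0 && !all(is.na(coverages)) &&
      all(coverages >= 5, na.rm = TRUE)
    warning("filter not set; defaulting to ", filter,
            " from the per-taxon coverages")
  }

  tables <- lapply(taxa, function(nm) {
    seqs <- read_taxon_sequences(taxa_cfg[[nm]]$files)
    count_kmers(seqs, k, nm, filter_singletons = filter)
  })
  names(tables) <- taxa

  paths <- list()
  if (isTRUE(config$write_table)) {
    paths$table <- file.path(out, "kmer_table.tsv")
    write_kmer_table(merge_kmer_tables(tables), paths$table)
  }

  M <- kmer_distance_matrix(tables, backsub = isTRUE(config$backsub))
  paths$matrix <- file.path(out, "distances.phylip")
  paths$counts <- file.path(out, "pair_counts.tsv")
  write_phylip(M, paths$matrix, sidecar = paths$counts)

  tree <- fit_tree(M)
  paths$tree <- file.path(out, "tree.nwk")
  ape::write.tree(tree, paths$tree)

  corrected <- NULL
  have_params <- !any(is.na(coverages))
  if (have_params) {
    params <- lapply(taxa, function(nm) {
      tx <- taxa_cfg[[nm]]
      sampling_params(tx$coverage, tx$read_length %||% 70,
                      tx$error_rate %||% 0.01, k, filter)
    })
    names(params) <- taxa
    n_t <- vapply(tables, `[[`, numeric(1), "n_distinct")
    corr <- average_tip_correction(params, n_t)
    corrected <- trim_tips(tree, corr)
    paths$tree_corrected <- file.path(out, "tree_tipcorrected.nwk")
    ape::write.tree(corrected, paths$tree_corrected)
  }

  boot <- NULL
  bs <- config$bootstrap
  if (!is.null(bs)) {
    mode <- bs$mode %||% "parametric"
    B <- bs$B %||% 100
    if (mode == "nonparametric") {
      reads <- lapply(taxa, function(nm)
        read_taxon_sequences(taxa_cfg[[nm]]$files))
      names(reads) <- taxa
      boot <- nonparametric_bootstrap(reads, k, filter, B = B,
                                      seed = bs$seed, ref_tree = tree)
    } else {
      if (!have_params)
        stop("parametric bootstrap needs coverage/read_length/error_rate per taxon")
      boot <- parametric_bootstrap(M, tree, params, B = B, seed = bs$seed)
    }
    paths$tree_bootstrap <- file.path(out, "tree_bootstrap.nwk")
    ape::write.tree(boot$tree, paths$tree_bootstrap)
    paths$support <- file.path(out, "support.tsv")
    write.table(boot$support, paths$support, sep = "\t", quote = FALSE,
                row.names = FALSE)
  }

  paths$report <- file.path(out, "report.txt")
  writeLines(c(
    paste0("aafphylo ", as.character(utils::packageVersion("aafphylo"))),
    paste0("k = ", k, "; singleton filter = ", filter,
           "; back-substitution correction = ", isTRUE(config$backsub)),
    paste0("seed = ", config$seed %||% "unset"),
    paste0("taxa (n_distinct k-mers):"),
    paste0("  ", taxa, ": ",
           vapply(tables, `[[`, numeric(1), "n_distinct")),
    if (have_params) paste0("tip correction applied: ",
                            signif(corr[1], 4)) else
      "tip correction skipped (no per-taxon sequencing parameters)",
    if (!is.null(boot)) paste0("bootstrap: ", bs$mode %||% "parametric",
                               ", B = ", bs$B %||% 100) else
      "bootstrap skipped"),
    paths$report)

  invisible(list(tables = tables, matrix = M, tree = tree,
                 tree_corrected = corrected, bootstrap = boot,
                 paths = paths))
}

`%||%` <- function(a, b) if (is.null(a)) b else a
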