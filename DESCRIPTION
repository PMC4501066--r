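Package: aafphylo
Title: Assembly- and Alignment-Free Phylogeny Reconstruction from Shared k-mers
Version: 0.1.0
Authors@R: person("Package", "Author", role = c("aut", "cre"), email = "author@example.org")
Description: Estimates pairwise evolutionary distances between genomes
    directly from the k-mers shared by raw sequencing reads or assemblies,
    fits an unrooted phylogeny by weighted least squares, and corrects and
    bootstraps the result using explicit models of k-mer homoplasy,
    incomplete sequencing coverage, and sequencing error. Includes the
    sequence-evolution and short-read simulators needed to validate every
    step without external data.
License: MIT + file LICENSE
Encoding: UTF-8
Imports:
    Rcpp,
    ape,
    phangorn,
    Biostrings,
    stats,
    utils,
    yaml
LinkingTo: Rcpp
Suggests:
    testthat (>= 3.0.0),
    withr,
    jsonlite,
    optparse
Config/testthat/edition: 3
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
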