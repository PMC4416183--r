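Package: kmerlda
Title: Alignment-Free Taxonomic Classification of DNA Sequences with
    k-mer Topic Models
Version: 0.1.0
Authors@R:
    person("Package", "Author", email = "author@example.org",
           role = c("aut", "cre"))
Description: Treats DNA sequences as bag-of-words documents over their
    overlapping k-mers and fits latent Dirichlet allocation (LDA) topic
    models to them by collapsed Gibbs sampling. Fitted topics are labeled
    with taxonomic ranks by majority vote over the training sequences
    assigned to each topic, and unknown sequences - including ultra-short
    fragments down to 25 bp - are classified by their most probable
    labeled topic, hierarchically from phylum down to family. Includes
    stratified cross-validation and fragment-robustness evaluation, and a
    synthetic taxonomy generator so the whole pipeline can be exercised
    without external reference databases.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Imports:
    Biostrings,
    jsonlite,
    Rcpp,
    stats,
    tools,
    utils
LinkingTo:
    Rcpp
Suggests:
    optparse,
    testthat (>= 3.0.0),
    withr
Config/testthat/edition: 3
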