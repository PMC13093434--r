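Package: codontax
Title: Alignment-Free Taxonomic Inference from Codon and Codon-Pair Usage
Version: 0.1.0
Authors@R: person("Package", "Author", email = "author@example.org", role = c("aut", "cre"))
Description: Tools for alignment-free taxonomic analysis of coding sequences.
    Extracts codon (64-dimensional) and codon-pair (4096-dimensional) usage
    profiles from CDS FASTA files or precomputed count tables, together with
    GC content and Shannon entropy summaries. Implements Taxonomic
    Consistency (TC), a rank-aware external clustering-validity index that
    scores a cluster assignment against a hierarchical reference taxonomy as
    the cluster-size-weighted Shannon entropy of reference labels within
    clusters. Includes an evaluation harness with species-blocked stratified
    train/test splits, train-only feature standardization, K-means and
    self-organizing-map clustering runners, Silhouette internal validation,
    pluggable supervised classifiers, and a seeded generator of synthetic
    clade-structured codon profiles for end-to-end testing.
License: MIT + file LICENSE
Encoding: UTF-8
Roxygen: list(markdown = TRUE)
RoxygenNote: 7.3.3
Depends: R (>= 4.1)
Imports:
    Biostrings,
    cluster,
    data.table,
    jsonlite,
    nnet,
    stats,
    utils
Suggests:
    e1071,
    randomForest,
    rpart,
    testthat (>= 3.0.0)
Config/testthat/edition: 3
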