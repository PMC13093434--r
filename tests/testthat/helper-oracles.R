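# Independent reference implementations used as oracles. These deliberately
# share no code with the package: character-by-character counting, joint
# contingency tables, and O(n^2) pairwise distances.

naive_count_codons <- function(sequences) {
  counts <- stats::setNames(integer(64), codon_names())
  for (s in toupper(sequences)) {
    n <- nchar(s) %/% 3
    if (n == 0) next
    for (i in seq_len(n)) {
      cod <- substr(s, 3 * i - 2, 3 * i)
      if (grepl("^[ACGT]{3}$", cod)) counts[cod] <- counts[cod] + 1L
    }
  }
  counts
}

naive_count_codon_pairs <- function(sequences) {
  counts <- stats::setNames(integer(4096), codon_pair_names())
  for (s in toupper(sequences)) {
    n <- nchar(s) %/% 3
    if (n < 2) next
    cods <- vapply(seq_len(n), function(i) substr(s, 3 * i - 2, 3 * i), "")
    ok <- grepl("^[ACGT]{3}$", cods)
    for (i in seq_len(n - 1)) {
      if (ok[i] && ok[i + 1]) {
        key <- paste0(cods[i], "-", cods[i + 1])
        counts[key] <- counts[key] + 1L
      }
    }
  }
  counts
}

# conditional entropy H(label | cluster) from the joint contingency table
conditional_entropy_oracle <- function(clusters, labels) {
  joint <- table(clusters, labels)
  n <- sum(joint)
  h <- 0
  for (k in rownames(joint)) {
    nk <- sum(joint[k, ])
    p <- joint[k, ] / nk
    p <- p[p > 0]
    h <- h + (nk / n) * (-sum(p * log2(p)))
  }
  h
}

brute_silhouette <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  d <- as.matrix(stats::dist(points))
  labels <- as.character(labels)
  s <- numeric(n)
  for (i in seq_len(n)) {
    own <- which(labels == labels[i])
    if (length(own) == 1) { s[i] <- 0; next }
    a <- mean(d[i, setdiff(own, i)])
    b <- min(vapply(setdiff(unique(labels), labels[i]),
                    function(l) mean(d[i, labels == l]), numeric(1)))
    s[i] <- (b - a) / max(a, b)
  }
  mean(s)
}

random_cds <- function(n, max_len = 300, ambig_prob = 0.02) {
  vapply(seq_len(n), function(i) {
    len <- sample.int(max_len, 1)
    paste(sample(c("A", "C", "G", "T", "N"), len, replace = TRUE,
                 prob = c(rep((1 - ambig_prob) / 4, 4), ambig_prob)),
          collapse = "")
  }, character(1))
}

# random clustering-vs-taxonomy instance for TC property tests
random_tc_instance <- function(n = 30, n_labels = 3, n_clusters = 4) {
  ids <- sprintf("o%03d", seq_len(n))
  labels <- sample(paste0("L", seq_len(n_labels)), n, replace = TRUE)
  tab <- taxonomy_table(
    data.frame(organism_id = ids, Parent = labels, stringsAsFactors = FALSE),
    ranks = "Parent")
  assignment <- stats::setNames(
    sample(paste0("c", seq_len(n_clusters)), n, replace = TRUE), ids)
  # guarantee preconditions: at least one organism per used cluster is
  # automatic; empty clusters are simply absent
  list(taxonomy = tab, assignment = assignment, labels = labels)
}

write_tsv_fixture <- function(df, path = tempfile(fileext = ".tsv")) {
  data.table::fwrite(df, path, sep = "\t", quote = FALSE)
  path
}

small_count_fixture <- function(n = 3, seed = 42, ranks = c("Domain", "Kingdom")) {
  set.seed(seed)
  counts <- matrix(rpois(n * 64, 10), nrow = n,
                   dimnames = list(NULL, codon_names()))
  df <- data.frame(organism_id = paste0("org", seq_len(n)),
                   stringsAsFactors = FALSE)
  for (r in ranks) df[[r]] <- paste0(substr(r, 1, 1), rep_len(1:2, n))
  cbind(df, as.data.frame(counts, check.names = FALSE))
}
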