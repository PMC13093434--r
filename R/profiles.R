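#' Codon and codon-pair vocabulary
#'
#' Canonical feature layouts for usage profiles. Codons are the 64 nucleotide
#' triplets in lexicographic order over the alphabet A < C < G < T; codon
#' pairs are the 4096 adjacent codon bigrams written `"AAA-AAA"` ...
#' `"TTT-TTT"`, where the pair `(c1, c2)` sits at index
#' `64 * (index(c1) - 1) + index(c2)`. Every count or frequency vector
#' produced by this package follows these layouts.
#'
#' @return Character vector of 64 codon names, or 4096 codon-pair names.
#' @examples
#' codon_names()[1:4]
#' codon_pair_names()[65] # first codon "AAC", second "AAA"
#' @export
codon_names <- function() {
  bases <- c("A", "C", "G", "T")
  grid <- expand.grid(b3 = bases, b2 = bases, b1 = bases,
                      stringsAsFactors = FALSE)
  paste0(grid$b1, grid$b2, grid$b3)
}

#' @rdname codon_names
#' @export
codon_pair_names <- function() {
  cods <- codon_names()
  grid <- expand.grid(c2 = cods, c1 = cods, stringsAsFactors = FALSE)
  paste0(grid$c1, "-", grid$c2)
}

profile_dim <- function(kind) switch(kind, codon = 64L, codon_pair = 4096L)

profile_feature_names <- function(kind) {
  switch(kind, codon = codon_names(), codon_pair = codon_pair_names())
}

#' Construct a coding-sequence set for one organism
#'
#' Bundles one organism's CDS nucleotide sequences under its identifier.
#' Sequences are uppercased; ambiguity codes (N, R, Y, ...) are allowed and
#' handled downstream by the counting rules.
#'
#' @param organism_id Non-empty organism identifier.
#' @param sequences Character vector of one or more nucleotide sequences
#'   (no whitespace).
#' @return An object of class `cds_set`.
#' @export
cds_set <- function(organism_id, sequences) {
  if (!is.character(organism_id) || length(organism_id) != 1L ||
      is.na(organism_id) || !nzchar(organism_id)) {
    stop("organism_id must be a single non-empty string")
  }
  sequences <- as.character(sequences)
  if (length(sequences) == 0L) {
    stop("at least one sequence is required for organism '", organism_id, "'")
  }
  if (any(grepl("[[:space:]]", sequences))) {
    stop("sequences must not contain whitespace (organism '", organism_id, "')")
  }
  structure(list(organism_id = organism_id, sequences = toupper(sequences)),
            class = "cds_set")
}

#' @export
print.cds_set <- function(x, ...) {
  cat(sprintf("<cds_set> %s: %d sequence(s), %d nt total\n",
              x$organism_id, length(x$sequences), sum(nchar(x$sequences))))
  invisible(x)
}

#' Read coding sequences from a FASTA file
#'
#' Reads a (possibly gzipped) multi-record FASTA file and groups records into
#' per-organism [cds_set] objects. With `group_by = "record"` every record is
#' its own organism, identified by the header text before the first
#' whitespace. With `group_by = "prefix"` records sharing the header prefix
#' before `delim` are pooled into one organism, so multiple CDS per genome
#' can live in one file (e.g. headers `org1|cds1`, `org1|cds2`).
#'
#' @param path Path to a FASTA file.
#' @param group_by Grouping rule, `"record"` (default) or `"prefix"`.
#' @param delim Delimiter for `group_by = "prefix"` (default `"|"`).
#' @return Named list of [cds_set] objects, in order of first appearance.
#' @export
read_cds_fasta <- function(path, group_by = c("record", "prefix"),
                           delim = "|") {
  group_by <- match.arg(group_by)
  if (!file.exists(path)) stop("FASTA file not found: ", path)
  first <- readLines(path, n = 1L)
  if (length(first) == 0L) stop("empty FASTA file: ", path)
  if (!startsWith(first, ">")) {
    stop("malformed FASTA (line 1 does not start with '>'): ", path)
  }
  seqs <- tryCatch(
    Biostrings::readDNAStringSet(path),
    error = function(e) stop("failed to parse FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE)
  )
  if (length(seqs) == 0L) stop("FASTA file contains no records: ", path)
  ids <- sub("\\s.*$", "", names(seqs))
  if (group_by == "prefix") {
    ids <- vapply(strsplit(ids, delim, fixed = TRUE), `[`, character(1), 1L)
  }
  chr <- toupper(as.character(seqs))
  groups <- split(unname(chr), factor(ids, levels = unique(ids)))
  lapply(stats::setNames(names(groups), names(groups)),
         function(id) cds_set(id, groups[[id]]))
}

#' Count codon or codon-pair occurrences in a coding-sequence set
#'
#' Each sequence is read in frame 0 as non-overlapping triplets. A trailing
#' remainder of 1-2 nt is dropped, and any triplet containing a character
#' outside A/C/G/T is skipped; both events are tallied and reported in a
#' warning and in the `"skipped"` attribute (number of complete triplet
#' windows lost to ambiguity). Codon pairs are the overlapping adjacent
#' bigrams `(c_i, c_i+1)` of the codon sequence -- `n - 1` pairs for an
#' n-codon CDS -- and never span sequence boundaries; a pair is skipped if
#' either of its codons was skipped.
#'
#' @param cds A [cds_set].
#' @return Named integer vector of length 64 ([count_codons]) or 4096
#'   ([count_codon_pairs]) in canonical order, with attributes `kind` and
#'   `skipped`.
#' @examples
#' count_codons(cds_set("x", "ATGATG"))[["ATG"]]
#' @export
count_codons <- function(cds) {
  stopifnot(inherits(cds, "cds_set"))
  dss <- Biostrings::DNAStringSet(cds$sequences)
  mat <- Biostrings::oligonucleotideFrequency(dss, width = 3L, step = 3L)
  counts <- as.integer(colSums(mat))
  names(counts) <- colnames(mat)
  counts <- counts[codon_names()]
  windows <- sum(nchar(cds$sequences) %/% 3L)
  skipped <- windows - sum(counts)
  if (skipped > 0L) {
    warning(sprintf("%d triplet(s) skipped (ambiguity codes) in organism '%s'",
                    skipped, cds$organism_id), call. = FALSE)
  }
  structure(counts, kind = "codon", skipped = skipped)
}

#' @rdname count_codons
#' @export
count_codon_pairs <- function(cds) {
  stopifnot(inherits(cds, "cds_set"))
  dss <- Biostrings::DNAStringSet(cds$sequences)
  mat <- Biostrings::oligonucleotideFrequency(dss, width = 6L, step = 3L)
  counts <- as.integer(colSums(mat))
  # 6-mer lexicographic order == (codon1, codon2) lexicographic order
  names(counts) <- paste0(substr(colnames(mat), 1L, 3L), "-",
                          substr(colnames(mat), 4L, 6L))
  counts <- counts[codon_pair_names()]
  ncod <- nchar(cds$sequences) %/% 3L
  windows <- sum(pmax(ncod - 1L, 0L))
  skipped <- windows - sum(counts)
  if (skipped > 0L) {
    warning(sprintf("%d codon pair(s) skipped (ambiguity codes) in organism '%s'",
                    skipped, cds$organism_id), call. = FALSE)
  }
  structure(counts, kind = "codon_pair", skipped = skipped)
}

#' Smooth and L1-normalize a count vector
#'
#' Applies the additive pseudo-count `alpha` to every cell and divides by the
#' smoothed total: `f_i = (c_i + alpha) / sum_j (c_j + alpha)`. With the
#' default `alpha = 1` every frequency is strictly positive, which stabilizes
#' rare (zero-count) codons and codon pairs before entropy or distance
#' computations.
#'
#' @param counts Non-negative numeric vector of counts.
#' @param alpha Pseudo-count, a single number >= 0. Default 1.
#' @return Numeric vector of relative frequencies summing to 1, names kept.
#' @export
normalize_profile <- function(counts, alpha = 1) {
  if (!is.numeric(alpha) || length(alpha) != 1L || is.na(alpha) || alpha < 0) {
    stop("alpha must be a single number >= 0")
  }
  counts <- as.numeric(counts)
  if (any(is.na(counts) | counts < 0)) stop("counts must be non-negative")
  total <- sum(counts) + alpha * length(counts)
  if (total <= 0) {
    stop("cannot normalize: all counts are zero and alpha = 0")
  }
  (counts + alpha) / total
}

#' GC content of a coding-sequence set
#'
#' Percentage of G and C among all unambiguous nucleotides pooled over the
#' set's sequences: `100 * (#G + #C) / (#A + #C + #G + #T)`. Ambiguity
#' characters are excluded from both numerator and denominator.
#'
#' @param cds A [cds_set].
#' @return GC percentage in \[0, 100\].
#' @export
gc_percent <- function(cds) {
  stopifnot(inherits(cds, "cds_set"))
  dss <- Biostrings::DNAStringSet(cds$sequences)
  lf <- colSums(Biostrings::letterFrequency(dss, letters = c("A", "C", "G", "T")))
  total <- sum(lf)
  if (total == 0) {
    stop("no unambiguous A/C/G/T nucleotides in organism '",
         cds$organism_id, "'")
  }
  100 * (lf[["G"]] + lf[["C"]]) / total
}

#' Shannon entropy of a frequency vector
#'
#' `H = -sum_i p_i log2 p_i` with the convention `0 * log 0 = 0`. Entropy is
#' reported in bits; a uniform distribution over d cells has entropy
#' `log2(d)` and a degenerate one has entropy 0.
#'
#' @param freqs Non-negative numeric vector summing to 1 (within 1e-6).
#' @return Entropy in bits.
#' @export
shannon_entropy <- function(freqs) {
  freqs <- as.numeric(freqs)
  if (any(is.na(freqs) | freqs < 0)) stop("frequencies must be non-negative")
  if (abs(sum(freqs) - 1) > 1e-6) {
    stop(sprintf("frequencies must sum to 1 (got %.8f)", sum(freqs)))
  }
  p <- freqs[freqs > 0]
  -sum(p * log2(p))
}

#' Full usage profile for one organism
#'
#' Convenience wrapper combining counting, pseudo-count smoothing, GC% and
#' Shannon entropy for one organism's CDS collection.
#'
#' @param cds A [cds_set].
#' @param kind `"codon"` or `"codon_pair"`.
#' @param alpha Pseudo-count passed to [normalize_profile()].
#' @param entropy_on Compute entropy on the `alpha`-smoothed frequencies
#'   (default) or on the raw relative frequencies with `0 log 0 = 0`.
#' @return A list of class `usage_profile` with elements `organism_id`,
#'   `kind`, `counts`, `freqs`, `alpha`, `gc_percent`, `entropy_bits` and
#'   `total_codons` (total counted units before smoothing).
#' @export
usage_profile <- function(cds, kind = c("codon", "codon_pair"), alpha = 1,
                          entropy_on = c("smoothed", "raw")) {
  kind <- match.arg(kind)
  entropy_on <- match.arg(entropy_on)
  counts <- if (kind == "codon") count_codons(cds) else count_codon_pairs(cds)
  freqs <- normalize_profile(counts, alpha = alpha)
  names(freqs) <- names(counts)
  hsrc <- if (entropy_on == "smoothed") freqs else {
    if (sum(counts) == 0) stop("raw entropy undefined: all counts zero")
    counts / sum(counts)
  }
  structure(list(organism_id = cds$organism_id, kind = kind,
                 counts = counts, freqs = freqs, alpha = alpha,
                 gc_percent = gc_percent(cds),
                 entropy_bits = shannon_entropy(hsrc),
                 total_codons = sum(counts)),
            class = "usage_profile")
}

#' @export
print.usage_profile <- function(x, ...) {
  cat(sprintf("<usage_profile> %s [%s]: %d units, GC%% = %.2f, H = %.3f bits\n",
              x$organism_id, x$kind, x$total_codons, x$gc_percent,
              x$entropy_bits))
  invisible(x)
}

# Metadata columns that are never taxonomic rank labels.
profile_non_rank_cols <- function() {
  c("organism_id", "species", "gc_percent", "entropy_bits", "total_codons")
}

#' Construct a profile table
#'
#' A profile table is a plain `data.frame` carrying one row per organism:
#' an `organism_id` column, optional metadata columns (`species` plus
#' taxonomic rank labels), and the 64 codon or 4096 codon-pair feature
#' columns in canonical order. The `kind` attribute records the feature
#' space.
#'
#' @param df A data.frame with `organism_id` and all feature columns.
#' @param kind `"codon"` or `"codon_pair"`.
#' @return The validated data.frame with class `profile_table` and
#'   attributes `kind` and `rank_columns`.
#' @export
profile_table <- function(df, kind = c("codon", "codon_pair")) {
  kind <- match.arg(kind)
  df <- as.data.frame(df)
  feats <- profile_feature_names(kind)
  missing <- setdiff(c("organism_id", feats), names(df))
  if (length(missing)) {
    stop("profile table is missing ", length(missing), " column(s): ",
         paste(utils::head(missing, 8), collapse = ", "),
         if (length(missing) > 8) ", ...")
  }
  if (anyDuplicated(df$organism_id)) {
    stop("duplicate organism_id in profile table: ",
         paste(unique(df$organism_id[duplicated(df$organism_id)]),
               collapse = ", "))
  }
  meta <- setdiff(names(df), feats)
  meta <- c("organism_id", setdiff(meta, "organism_id"))
  df <- df[, c(meta, feats)]
  ranks <- setdiff(meta, profile_non_rank_cols())
  structure(df, kind = kind, rank_columns = ranks,
            class = c("profile_table", "data.frame"))
}

#' Extract the feature matrix from a profile table
#'
#' @param table A [profile_table].
#' @return Numeric matrix (organisms x features) with organism_id rownames.
#' @export
profile_matrix <- function(table) {
  stopifnot(inherits(table, "profile_table"))
  feats <- profile_feature_names(attr(table, "kind"))
  m <- as.matrix(as.data.frame(table)[, feats])
  storage.mode(m) <- "double"
  rownames(m) <- table$organism_id
  m
}

#' Read a delimited codon / codon-pair count (or frequency) table
#'
#' Parses a CoCoPUTs-style delimited text file (TSV or CSV, autodetected)
#' with a header row naming an `organism_id` column and the 64 codon or 4096
#' codon-pair feature columns; extra metadata columns (`species`, rank
#' labels) are kept. Exact duplicate rows are removed. If `ranks` are
#' requested, rows with a missing/blank label at any of those ranks are
#' dropped; the number dropped is reported via a message and stored in the
#' `"dropped"` attribute.
#'
#' @param path Path to the delimited file.
#' @param kind `"codon"` or `"codon_pair"`.
#' @param ranks Optional character vector of rank columns that must be
#'   non-missing.
#' @return A [profile_table].
#' @export
read_count_table <- function(path, kind = c("codon", "codon_pair"),
                             ranks = NULL) {
  kind <- match.arg(kind)
  if (!file.exists(path)) stop("count table not found: ", path)
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  if ("organism_id" %in% names(df)) df$organism_id <- as.character(df$organism_id)
  feats <- profile_feature_names(kind)
  missing <- setdiff(feats, names(df))
  if (length(missing)) {
    stop("count table is missing ", length(missing), " ", kind,
         " column(s): ", paste(utils::head(missing, 8), collapse = ", "),
         if (length(missing) > 8) ", ...")
  }
  if (!"organism_id" %in% names(df)) stop("count table lacks 'organism_id'")
  df <- df[!duplicated(df), , drop = FALSE]
  dropped <- 0L
  if (!is.null(ranks)) {
    miss_rank <- setdiff(ranks, names(df))
    if (length(miss_rank)) {
      stop("count table lacks requested rank column(s): ",
           paste(miss_rank, collapse = ", "))
    }
    ok <- Reduce(`&`, lapply(df[ranks], function(v) !is.na(v) & nzchar(trimws(v))))
    dropped <- sum(!ok)
    if (dropped > 0L) {
      message(dropped, " row(s) dropped for missing labels at rank(s): ",
              paste(ranks, collapse = ", "))
    }
    df <- df[ok, , drop = FALSE]
  }
  out <- profile_table(df, kind = kind)
  attr(out, "dropped") <- dropped
  out
}

#' Write a profile table to delimited text
#'
#' Writes tab-separated text with a header row. Numeric values are written
#' with 15 significant digits, so a write/read round trip reproduces count
#' tables exactly and frequency tables to well within 1e-10.
#'
#' @param table A [profile_table].
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_profile_table <- function(table, path) {
  stopifnot(inherits(table, "profile_table"))
  data.table::fwrite(as.data.frame(table), path, sep = "\t", quote = FALSE)
  invisible(path)
}

#' Build a profile table from a FASTA file
#'
#' End-to-end feature extraction: read CDS, count, smooth, and assemble one
#' frequency row per organism with `gc_percent`, `entropy_bits` and
#' `total_codons` summary columns.
#'
#' @inheritParams read_cds_fasta
#' @inheritParams usage_profile
#' @return A data.frame: `organism_id`, `gc_percent`, `entropy_bits`,
#'   `total_codons`, then the feature frequency columns.
#' @export
profile_fasta <- function(path, kind = c("codon", "codon_pair"), alpha = 1,
                          group_by = c("record", "prefix"), delim = "|",
                          entropy_on = c("smoothed", "raw")) {
  kind <- match.arg(kind)
  sets <- read_cds_fasta(path, group_by = group_by, delim = delim)
  profs <- lapply(sets, usage_profile, kind = kind, alpha = alpha,
                  entropy_on = entropy_on)
  meta <- data.frame(
    organism_id = vapply(profs, `[[`, character(1), "organism_id"),
    gc_percent = vapply(profs, `[[`, numeric(1), "gc_percent"),
    entropy_bits = vapply(profs, `[[`, numeric(1), "entropy_bits"),
    total_codons = vapply(profs, function(p) as.integer(p$total_codons),
                          integer(1)),
    stringsAsFactors = FALSE
  )
  freqs <- do.call(rbind, lapply(profs, `[[`, "freqs"))
  rownames(meta) <- NULL
  cbind(meta, as.data.frame(freqs, check.names = FALSE))
}
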