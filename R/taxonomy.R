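#' Default taxonomic ranks
#'
#' The ordered rank list used throughout the package, highest rank first.
#'
#' @return `c("Domain", "Kingdom", "Phylum", "Class", "Order")`
#' @export
default_ranks <- function() c("Domain", "Kingdom", "Phylum", "Class", "Order")

#' Construct a taxonomy table
#'
#' A taxonomy table maps each organism to one label per rank of an ordered
#' rank list (highest first), e.g. Domain through Order. Labels must be
#' complete: organisms missing any rank label are rejected here and filtered
#' with a report by [read_lineage_table()].
#'
#' @param df data.frame with `organism_id` and one column per rank.
#' @param ranks Ordered character vector of rank names, highest first.
#' @return The data.frame with class `taxonomy_table` and attribute `ranks`.
#' @export
taxonomy_table <- function(df, ranks = default_ranks()) {
  df <- as.data.frame(df)
  if (!length(ranks) || anyDuplicated(ranks)) {
    stop("ranks must be a non-empty list of unique names")
  }
  missing <- setdiff(c("organism_id", ranks), names(df))
  if (length(missing)) {
    stop("taxonomy table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[, c("organism_id", ranks), drop = FALSE]
  df$organism_id <- as.character(df$organism_id)
  for (r in ranks) df[[r]] <- as.character(df[[r]])
  bad <- Reduce(`|`, lapply(df[ranks], function(v) is.na(v) | !nzchar(trimws(v))))
  if (any(bad)) {
    stop(sum(bad), " organism(s) have missing rank labels; ",
         "filter before constructing (see read_lineage_table)")
  }
  if (anyDuplicated(df$organism_id)) {
    stop("duplicate organism_id: ",
         paste(unique(df$organism_id[duplicated(df$organism_id)]),
               collapse = ", "))
  }
  structure(df, ranks = ranks, class = c("taxonomy_table", "data.frame"))
}

#' Read an organism lineage table
#'
#' Parses a delimited text file (TSV or CSV, autodetected) with columns
#' `organism_id` plus one label column per requested rank. Rows with an
#' empty or NA label at any requested rank are dropped and counted
#' (reported via a message and the `"dropped"` attribute); exact duplicate
#' rows are collapsed to one.
#'
#' @param path Path to the lineage file.
#' @param ranks Ordered rank names, highest first.
#' @return A [taxonomy_table].
#' @export
read_lineage_table <- function(path, ranks = default_ranks()) {
  if (!file.exists(path)) stop("lineage table not found: ", path)
  df <- as.data.frame(data.table::fread(path, header = TRUE))
  missing <- setdiff(c("organism_id", ranks), names(df))
  if (length(missing)) {
    stop("lineage table is missing column(s): ",
         paste(missing, collapse = ", "))
  }
  df <- df[, c("organism_id", ranks), drop = FALSE]
  df$organism_id <- as.character(df$organism_id)
  for (r in ranks) df[[r]] <- as.character(df[[r]])
  df <- df[!duplicated(df), , drop = FALSE]
  ok <- Reduce(`&`, lapply(df[ranks], function(v) !is.na(v) & nzchar(trimws(v))))
  dropped <- sum(!ok)
  if (dropped > 0L) {
    message(dropped, " row(s) dropped for missing rank labels")
  }
  out <- taxonomy_table(df[ok, , drop = FALSE], ranks = ranks)
  attr(out, "dropped") <- dropped
  out
}

#' Project taxonomy labels at one rank
#'
#' @param table A [taxonomy_table].
#' @param rank One of the table's rank names.
#' @return Named character vector `organism_id -> label`.
#' @export
labels_at_rank <- function(table, rank) {
  stopifnot(inherits(table, "taxonomy_table"))
  ranks <- attr(table, "ranks")
  if (!(rank %in% ranks)) {
    stop("unknown rank '", rank, "'; available: ",
         paste(ranks, collapse = ", "))
  }
  stats::setNames(table[[rank]], table$organism_id)
}

#' Build the taxonomy tree implied by a lineage table
#'
#' Nodes are keyed by the full label path from the root, so a label reused
#' under two different parents yields two distinct nodes (NCBI labels are
#' not unique across lineages). Organisms hang as leaves under their
#' lowest-rank node; `leaf_count` at every internal node is the number of
#' organisms below it, and is conserved (parent = sum over children).
#'
#' @param table A [taxonomy_table].
#' @return A list of class `taxonomy_tree`: `nodes` (data.frame with
#'   `node_id` = "/"-joined label path, `rank`, `label`, `parent_id`,
#'   `leaf_count`, rows sorted by `node_id`), `leaves` (data.frame
#'   `organism_id`, `node_id`), and `ranks`.
#' @export
build_tree <- function(table) {
  stopifnot(inherits(table, "taxonomy_table"))
  ranks <- attr(table, "ranks")
  paths <- Reduce(function(acc, r) paste(acc, table[[r]], sep = "/"),
                  ranks, accumulate = TRUE,
                  init = character(nrow(table)))[-1]
  names(paths) <- NULL
  nodes <- do.call(rbind, lapply(seq_along(ranks), function(i) {
    p <- substring(paths[[i]], 2L) # drop leading "/"
    parent <- if (i == 1L) rep("<root>", length(p)) else
      substring(paths[[i - 1L]], 2L)
    agg <- stats::aggregate(list(leaf_count = rep(1L, length(p))),
                            by = list(node_id = p, parent_id = parent),
                            FUN = sum)
    data.frame(node_id = agg$node_id, rank = ranks[i],
               label = table[[ranks[i]]][match(agg$node_id, p)],
               parent_id = agg$parent_id, leaf_count = agg$leaf_count,
               stringsAsFactors = FALSE)
  }))
  nodes <- nodes[order(nodes$node_id), , drop = FALSE]
  rownames(nodes) <- NULL
  leaves <- data.frame(organism_id = table$organism_id,
                       node_id = substring(paths[[length(ranks)]], 2L),
                       stringsAsFactors = FALSE)
  leaves <- leaves[order(leaves$organism_id), , drop = FALSE]
  rownames(leaves) <- NULL
  structure(list(nodes = nodes, leaves = leaves, ranks = ranks),
            class = "taxonomy_tree")
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat(sprintf("<taxonomy_tree> %d node(s) over ranks %s; %d organism leaves\n",
              nrow(x$nodes), paste(x$ranks, collapse = " > "),
              nrow(x$leaves)))
  invisible(x)
}

#' Export a taxonomy tree to Newick
#'
#' Leaf names are organism identifiers; internal node labels are the rank
#' labels (last path component). Intended for quick inspection in standard
#' tree viewers, not for branch-length analysis (all branch lengths are
#' omitted).
#'
#' @param tree A [build_tree()] result.
#' @return A single Newick string, terminated by ";".
#' @export
tree_to_newick <- function(tree) {
  stopifnot(inherits(tree, "taxonomy_tree"))
  esc <- function(x) gsub("[ ,;:()\\[\\]']", "_", x)
  recurse <- function(id) {
    kids <- tree$nodes$node_id[tree$nodes$parent_id == id]
    orgs <- tree$leaves$organism_id[tree$leaves$node_id == id]
    parts <- c(vapply(sort(kids), recurse, character(1)), esc(sort(orgs)))
    lab <- if (id == "<root>") "" else esc(sub("^.*/", "", id))
    if (!length(parts)) return(lab)
    paste0("(", paste(parts, collapse = ","), ")", lab)
  }
  paste0(recurse("<root>"), ";")
}
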