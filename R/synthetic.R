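#' Specification for a synthetic clade-structured dataset
#'
#' Describes a multi-rank taxonomy together with clade-correlated codon (or
#' codon-pair) frequency vectors. The generating model mirrors the working
#' assumption behind compositional taxonomic inference: related organisms
#' have similar usage distributions, with similarity decaying across
#' taxonomic levels.
#'
#' A root composition is drawn from a symmetric Dirichlet prior
#' (`concentration`); each child taxon perturbs its parent's composition by
#' logistic-normal jitter (Gaussian noise of scale `drift` on log
#' frequencies, then renormalization). Below the lowest rank, each leaf
#' taxon holds `species_per_leaf` species, each with its own jittered
#' vector; all `strains_per_species` strains of a species share the species
#' vector, and each strain's counts are one multinomial draw of depth
#' `total_units` from it. `drift` may be a single scale or one scale per
#' level (ranks first, then the species level; recycled if shorter), so
#' between-clade separation and within-clade spread can be controlled
#' independently.
#'
#' @param ranks Ordered rank names, highest first.
#' @param branching Integer children per node at each rank (recycled).
#' @param species_per_leaf Species per lowest-rank taxon.
#' @param strains_per_species Organisms (strains) per species.
#' @param concentration Symmetric Dirichlet concentration for the root
#'   composition (> 0); larger = closer to uniform.
#' @param drift Per-level log-scale perturbation (>= 0); scalar or vector
#'   of length `length(ranks) + 1` (last entry = species level).
#' @param kind `"codon"` (64-D) or `"codon_pair"` (4096-D).
#' @param total_units Multinomial depth per organism (codons counted).
#' @param seed Integer seed; generation is fully deterministic given it.
#' @return A list of class `synthetic_spec`.
#' @export
synthetic_spec <- function(ranks = c("Domain", "Kingdom"),
                           branching = c(3L, 2L), species_per_leaf = 4L,
                           strains_per_species = 3L, concentration = 50,
                           drift = 0.5, kind = c("codon", "codon_pair"),
                           total_units = 50000L, seed = 1L) {
  kind <- match.arg(kind)
  if (!length(ranks)) stop("ranks must be non-empty")
  branching <- rep_len(as.integer(branching), length(ranks))
  if (any(branching < 1L) || species_per_leaf < 1L ||
      strains_per_species < 1L || total_units < 1L) {
    stop("branching, species_per_leaf, strains_per_species and total_units must be >= 1")
  }
  if (concentration <= 0) stop("concentration must be > 0")
  drift <- rep_len(as.numeric(drift), length(ranks) + 1L)
  if (any(drift < 0)) stop("drift must be >= 0")
  structure(list(ranks = ranks, branching = branching,
                 species_per_leaf = as.integer(species_per_leaf),
                 strains_per_species = as.integer(strains_per_species),
                 concentration = concentration, drift = drift, kind = kind,
                 total_units = as.integer(total_units),
                 seed = as.integer(seed)),
            class = "synthetic_spec")
}

# logistic-normal jitter: perturb log-frequencies and renormalize
jitter_composition <- function(p, scale) {
  if (scale == 0) return(p)
  lp <- log(p) + stats::rnorm(length(p), 0, scale)
  lp <- lp - max(lp)
  e <- exp(lp)
  e / sum(e)
}

#' Generate a synthetic clade-structured dataset
#'
#' Realizes a [synthetic_spec()]: builds the taxonomy, draws the
#' hierarchically perturbed frequency vectors, and samples per-organism
#' count profiles. For `kind = "codon_pair"` each species' 4096-D pair
#' composition is the outer product of its 64-D codon composition modulated
#' by separable log-normal noise (row and column factors of scale equal to
#' the species-level drift), so pair profiles stay consistent with the
#' codon marginals while gaining pair-specific structure.
#'
#' @param spec A [synthetic_spec()].
#' @return A list of class `synthetic_dataset`: `profiles` (a
#'   [profile_table] of counts with `species` and rank label columns),
#'   `taxonomy` (a [taxonomy_table]), `true_frequencies` (named list of the
#'   generating composition per taxon node and species) and `spec`.
#' @export
generate_synthetic <- function(spec) {
  stopifnot(inherits(spec, "synthetic_spec"))
  dim <- profile_dim(spec$kind)
  base_dim <- 64L
  rng <- make_rng(spec$seed)
  withr_rng(rng, function() {
    root <- stats::rgamma(base_dim, shape = spec$concentration)
    root <- root / sum(root)
    # expand the taxonomy level by level; keep each node's composition
    nodes <- list(list(labels = character(0), p = root))
    true_freqs <- list()
    for (lev in seq_along(spec$ranks)) {
      rank_letter <- substr(spec$ranks[lev], 1L, 1L)
      nxt <- list()
      for (node in nodes) {
        for (child in seq_len(spec$branching[lev])) {
          lab <- if (lev == 1L) paste0(rank_letter, child) else
            paste0(node$labels[length(node$labels)], ".", rank_letter, child)
          p <- jitter_composition(node$p, spec$drift[lev])
          true_freqs[[lab]] <- p
          nxt[[length(nxt) + 1L]] <- list(labels = c(node$labels, lab), p = p)
        }
      }
      nodes <- nxt
    }
    sp_drift <- spec$drift[length(spec$ranks) + 1L]
    tax_rows <- list()
    count_rows <- list()
    org_meta <- list()
    for (node in nodes) {
      for (s in seq_len(spec$species_per_leaf)) {
        sp_id <- paste0("sp_", node$labels[length(node$labels)], "_", s)
        sp_p <- jitter_composition(node$p, sp_drift)
        if (spec$kind == "codon_pair") {
          u <- exp(stats::rnorm(base_dim, 0, sp_drift))
          v <- exp(stats::rnorm(base_dim, 0, sp_drift))
          pair <- as.vector(t((sp_p * u) %o% (sp_p * v)))
          sp_p <- pair / sum(pair)
        }
        stopifnot(length(sp_p) == dim)
        true_freqs[[sp_id]] <- sp_p
        for (st in seq_len(spec$strains_per_species)) {
          org <- paste0("org_", node$labels[length(node$labels)],
                        "_", s, "_", st)
          counts <- as.integer(stats::rmultinom(1L, spec$total_units, sp_p))
          i <- length(org_meta) + 1L
          org_meta[[i]] <- c(organism_id = org, species = sp_id,
                             stats::setNames(node$labels, spec$ranks))
          count_rows[[i]] <- counts
        }
      }
    }
    meta <- as.data.frame(do.call(rbind, org_meta), stringsAsFactors = FALSE)
    counts <- do.call(rbind, count_rows)
    colnames(counts) <- profile_feature_names(spec$kind)
    profiles <- profile_table(cbind(meta, as.data.frame(counts, check.names = FALSE)),
                              kind = spec$kind)
    taxonomy <- taxonomy_table(meta[, c("organism_id", spec$ranks)],
                               ranks = spec$ranks)
    structure(list(profiles = profiles, taxonomy = taxonomy,
                   true_frequencies = true_freqs, spec = spec),
              class = "synthetic_dataset")
  })
}

#' @export
print.synthetic_dataset <- function(x, ...) {
  cat(sprintf("<synthetic_dataset> %s, %d organism(s), ranks %s, seed %d\n",
              x$spec$kind, nrow(x$profiles),
              paste(x$spec$ranks, collapse = " > "), x$spec$seed))
  invisible(x)
}

#' Smoothed frequency matrix of a dataset's profiles
#'
#' Applies [normalize_profile()] row-wise to the count table, yielding the
#' feature matrix consumed by clustering and classification.
#'
#' @param dataset A `synthetic_dataset`, or any [profile_table] of counts.
#' @param alpha Pseudo-count. Default 1.
#' @return Numeric matrix (organisms x features), organism_id rownames.
#' @export
frequency_matrix <- function(dataset, alpha = 1) {
  table <- if (inherits(dataset, "synthetic_dataset")) dataset$profiles else dataset
  m <- profile_matrix(table)
  t(apply(m, 1L, normalize_profile, alpha = alpha))
}
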