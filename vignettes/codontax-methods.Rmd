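---
title: "Methods: codon-usage profiles and the Taxonomic Consistency index"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: codon-usage profiles and the Taxonomic Consistency index}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(codontax)
```

## The representation

`codontax` represents an organism's coding sequences by their codon usage
(a 64-dimensional vector of triplet relative frequencies) or codon-pair
usage (4096-dimensional, over adjacent codon bigrams). Both are
length-normalized compositional signatures: they do not depend on how much
sequence was observed, only on its composition, and they carry phylogenetic
signal because codon preferences evolve with the lineage.

Counting rules, and why they look the way they do:

* **Frame and remainders.** CDS are assumed in-frame, so each sequence is
  read from position 1 in non-overlapping triplets; a trailing remainder of
  1–2 nt is dropped. Truncation is silent in the counts but logged (a
  warning plus a `skipped` attribute), because an unexpected remainder
  usually means a mis-annotated CDS.
* **Ambiguity codes.** A triplet containing any non-ACGT character is
  skipped rather than guessed, so the 64-letter alphabet is never biased by
  ambiguous base calls. A codon pair is skipped if either of its codons
  was.
* **Pairs are overlapping bigrams.** An n-codon CDS contributes n − 1
  pairs (c~i~, c~i+1~), the standard codon-pair-bias convention;
  non-overlapping pairing would halve the counts and lose half the
  adjacency information. Pairs never span CDS boundaries, since the
  junction between two CDS is not a biological adjacency.
* **Pseudo-count.** Before L1 normalization an additive pseudo-count
  α (default 1) is applied to every cell:
  f~i~ = (c~i~ + α) / Σ~j~(c~j~ + α). This stabilizes rare events —
  essential in the 4096-dimensional pair space, where many cells are empty
  at realistic sequencing depth — and guarantees strictly positive
  frequencies, so entropies and log-ratios are always defined. Count
  tables read from disk are treated as raw and smoothed here, never
  assumed pre-smoothed.
* **Summaries.** GC% is the fraction of G+C among unambiguous nucleotides
  (a length-independent global composition baseline), and the Shannon
  entropy H = −Σ p~i~ log₂ p~i~ summarizes how spread out usage is. All
  entropies in this package are base-2 (bits): the worked example below
  (0.918 for proportions 2/3, 1/3) pins the base unambiguously. By
  default H is computed on the α-smoothed frequencies, consistent with
  the features the models consume; `entropy_on = "raw"` computes it on raw
  proportions with 0·log 0 ≡ 0.

## The Taxonomic Consistency index

Standard external indices (ARI, NMI, purity) assume a flat label space.
TC instead evaluates a clustering against each rank of the taxonomic
hierarchy separately. For one rank, each cluster j gets a **Node Entropy**

$$\mathrm{NE}_j = -\sum_i p_i \log_2 p_i,$$

the entropy of the reference labels among its members, and the clustering
gets the size-weighted aggregate

$$\mathrm{TC} = \sum_j \frac{n_j}{N}\,\mathrm{NE}_j,$$

which is exactly the conditional entropy H(label | cluster) in bits. TC is
0 iff every cluster is pure, invariant to renaming clusters or labels,
and bounded above by log₂ of the number of labels at the rank. The package
verifies the algebra against a brute-force contingency-table oracle in its
test suite.

```{r worked-example}
fx <- worked_example_fixture()
tc_score(fx$assignment, fx$taxonomy, fx$rank)
```

Design choices worth stating explicitly:

* **Flat per-rank TC is canonical.** The hierarchy is handled by computing
  an independent TC at each rank (`tc_by_rank()`) rather than by a
  recursive cross-rank blend. The per-rank decomposition is what the
  worked example above exercises and what a user can interpret
  (one number per rank, comparable across runs); a recursive blended score
  has no printed reference behavior to anchor it. No monotonicity across
  ranks is enforced — finer ranks usually score higher, but the report
  shows what was measured.
* **Probabilities are member proportions.** p~i~ is the fraction of a
  cluster's members carrying reference label i; this is the only reading
  consistent with NE values like 0.918 for a 2:1 cluster.
* **Partial assignments.** Organisms in the taxonomy but not in the
  assignment are ignored (clustering tools may drop rows), and the covered
  fraction is reported so the asymmetry is visible rather than silent.
* **Precision.** Human-readable output rounds to 3 decimals; machine
  output keeps full precision.

## Evaluation protocol

* **Species-blocked splits.** `species_split()` assigns every species
  wholly to train or test (default test fraction 0.2), so strains of one
  species can never leak across the split. Within each stratum (class of
  the target rank) species are allocated greedily, largest strain-count
  first with seeded tie-breaking, until the stratum's test-row target is
  reached — deterministic given the seed and close to the target fraction
  under blocking. A single-species stratum goes to train with a warning.
  The split is computed once and reused across ranks so results are
  comparable.
* **Train-only standardization.** `fit_standardizer()` estimates
  per-feature mean and SD on training rows only; test rows are transformed
  with the same model. Constant features (common as all-zero codon-pair
  columns on small data) map to zero rather than erroring.
* **Clustering runners.** K-means uses the standard library implementation
  with seeded restarts. The SOM is a deliberately minimal online
  implementation: best-matching unit by Euclidean distance, Gaussian
  neighborhood on the lattice, learning rate and radius decaying linearly
  to 1% of their initial values over the run. The default lattice is
  1 × K, which makes "number of clusters" directly comparable between SOM
  and K-means sweeps. With `epochs = 0` points are mapped onto the seeded
  initial weights, which gives tests a no-training contract to pin
  determinism.
* **Dual validation.** `evaluate_clustering()` reports the Silhouette
  coefficient (internal: cohesion vs. separation in feature space,
  singleton clusters score 0) next to TC per rank (external). High
  Silhouette with low TC indicates geometry that also respects taxonomy;
  disagreement between the two is itself informative.
* **Classifiers are adapters.** The supervised harness takes any object
  with `fit(x, y)` / `predict(model, x)`; multinomial logistic regression
  ships as the default, with random-forest, SVM and decision-tree adapters
  available when the corresponding packages are installed. No
  hyperparameter grids are pinned — tuning is the caller's concern, and an
  adapter can wrap a tuned pipeline.

## The synthetic-data generator

`generate_synthetic()` emulates the one assumption the whole approach
rests on: organisms with recent common ancestry have similar usage
distributions, with similarity decaying across taxonomic levels.

The generating model: a root 64-dim composition is drawn from a symmetric
Dirichlet (concentration 50, giving mild codon bias around uniform); each
child taxon applies logistic-normal jitter to its parent — Gaussian noise
of scale `drift` on log frequencies, renormalized — one scale per level,
with the species level last; strains of a species share the species vector
and differ only by multinomial sampling noise at depth `total_units`
(default 50,000 codons, a small bacterial genome's worth). Logistic-normal
jitter was chosen over Dirichlet resampling because it gives a single
interpretable similarity knob per level: `drift` is the log-scale
divergence between parent and child. Codon-pair mode builds each species'
4096-dim composition as the outer product of its codon composition
modulated by separable log-normal row/column noise — cheap, marginally
consistent, and sufficient to exercise the 4096-D plumbing; full
sequence-level simulation is not attempted.

What this emulates — clade-correlated compositions at controllable
separation, strain replication, multinomial count noise — and what it does
not: real genomes have amino-acid-driven constraints, GC gradients,
horizontal transfer, and wildly uneven clade sizes. Passing recovery tests
on this generator shows the pipeline is correct and sensitive at a given
separation; it does not certify accuracy on real data.

Test problem sizes are kept modest (tens of organisms, 5–10k codons,
10 seeds for recovery experiments); these sizes already give stable
verdicts for the properties checked, e.g. mean TC(Domain) < 0.1 when
domain-level drift (1.2) dominates within-domain drift (0.15).

## Numerical and degenerate-input choices

* `normalize_profile()` with α = 0 on all-zero counts is an error (the
  distribution is undefined), not a silent uniform.
* `shannon_entropy()` validates non-negativity and Σp = 1 (tolerance
  1e-6) rather than renormalizing silently.
* K-means at the boundaries: k = 1 returns one cluster with the mean as
  centroid; k = n returns each point as its own cluster (the library
  routine rejects this case, so it is handled explicitly).
* Silhouette requires n ≥ 3 and ≥ 2 clusters; singleton clusters
  contribute 0, the common convention.
* Taxonomy nodes are keyed by the full label path from the root, so a
  label reused under two parents (homonymous taxa) yields two distinct
  nodes.
* All stochastic components (splits, K-means, SOM, the generator) consume
  explicit integer seeds through a private RNG scope, so runs are
  reproducible and never disturb the caller's RNG state.

## Known limitations

* TC has no significance test attached; compare values across runs, not
  against a null.
* Family-blocked evaluation (blocking at coarser ranks than species) is
  not implemented; closely related species can still induce optimistic
  supervised estimates at fine ranks.
* The SOM is minimal by design (rectangular lattice, Gaussian
  neighborhood, linear decay); it is a clustering baseline, not a
  topology-preserving visualization tool.
* Viral lineages, organellar genomes, and rank-gap taxonomies are not
  special-cased: the lineage loader requires complete labels at the
  requested ranks and reports what it drops.
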