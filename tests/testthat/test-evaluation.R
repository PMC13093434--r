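make_meta <- function(n_species, strains = 4, classes = 1) {
  sp <- sprintf("sp%03d", seq_len(n_species))
  data.frame(
    organism_id = sprintf("org%04d", seq_len(n_species * strains)),
    species = rep(sp, each = strains),
    Domain = rep(rep(paste0("D", seq_len(classes)), length.out = n_species),
                 each = strains),
    stringsAsFactors = FALSE
  )
}

test_that("species never straddle the split and fractions are on target", {
  meta <- make_meta(10, strains = 3)
  sp <- species_split(meta, test_fraction = 0.2, stratify_rank = "Domain",
                      seed = 1)
  expect_length(sp$test, 6) # 2 species x 3 strains
  test_species <- unique(meta$species[meta$organism_id %in% sp$test])
  train_species <- unique(meta$species[meta$organism_id %in% sp$train])
  expect_length(intersect(test_species, train_species), 0)
  expect_setequal(c(sp$train, sp$test), meta$organism_id)
})

test_that("stratified split draws test species from every class", {
  meta <- make_meta(10, strains = 2, classes = 2) # 5 species per class
  sp <- species_split(meta, test_fraction = 0.2, stratify_rank = "Domain",
                      seed = 3)
  test_sp <- unique(meta[meta$organism_id %in% sp$test, c("species", "Domain")])
  expect_equal(unname(table(test_sp$Domain)[c("D1", "D2")]),
               unname(c(1L, 1L)), ignore_attr = TRUE)
})

test_that("single-species strata go to train with a warning", {
  meta <- make_meta(1, strains = 2) # one stratum, one species
  expect_warning(sp <- species_split(meta, stratify_rank = "Domain"),
                 "single species")
  expect_length(sp$test, 0)
  expect_length(sp$train, 2)
})

test_that("splits are deterministic in the seed and vary across seeds", {
  meta <- make_meta(20, strains = 2)
  a <- species_split(meta, stratify_rank = "Domain", seed = 9)
  b <- species_split(meta, stratify_rank = "Domain", seed = 9)
  expect_identical(a, b)
  many <- vapply(1:20, function(s) {
    paste(sort(species_split(meta, stratify_rank = "Domain", seed = s)$test),
          collapse = ",")
  }, character(1))
  expect_gt(length(unique(many)), 1)
})

test_that("standardizer fits on train only and applies its affine map", {
  x <- matrix(c(0, 2, 0, 2), nrow = 2) # two features, values {0, 2}
  m <- fit_standardizer(x)
  z <- apply_standardizer(m, x)
  expect_equal(as.vector(z), rep(c(-1, 1) / sqrt(2), 2), tolerance = 1e-12)
  expect_equal(colMeans(z), c(0, 0), tolerance = 1e-9)

  # constant feature maps to zero with a warning
  xc <- cbind(c(1, 2, 3), c(5, 5, 5))
  expect_warning(mc <- fit_standardizer(xc), "constant")
  expect_equal(apply_standardizer(mc, xc)[, 2], rep(0, 3))

  # unseen rows use the training statistics, not their own
  unseen <- matrix(c(10, 10), nrow = 1)
  expect_equal(as.vector(apply_standardizer(m, unseen)),
               (10 - m$mean) / m$sd, ignore_attr = TRUE)
  expect_error(fit_standardizer(x[1, , drop = FALSE]), "at least 2")

  # leakage check: refitting with extra rows changes the parameters
  m2 <- fit_standardizer(rbind(x, unseen))
  expect_false(isTRUE(all.equal(m$mean, m2$mean)))
})

test_that("silhouette matches the brute-force oracle and its edge cases", {
  pts <- matrix(c(0, 0.1, 10, 10.1), ncol = 1)
  lab <- c("A", "A", "B", "B")
  # frozen from the brute-force oracle: a = 0.1, b = 10.05 for the tight
  # pair, s = (10.05 - 0.1) / 10.05, mean = 0.990
  s <- silhouette_score(pts, lab)
  expect_equal(s, 0.990, tolerance = 1e-3)
  expect_equal(s, brute_silhouette(pts, lab), tolerance = 1e-9)

  set.seed(77)
  for (i in 1:10) {
    n <- sample(10:60, 1)
    p <- matrix(rnorm(n * 3), ncol = 3)
    l <- sample(letters[1:sample(2:4, 1)], n, replace = TRUE)
    if (length(unique(l)) < 2) next
    expect_equal(silhouette_score(p, l), brute_silhouette(p, l),
                 tolerance = 1e-9)
  }

  ident <- matrix(rep(c(1, 2), each = 4), ncol = 2)
  expect_lte(silhouette_score(ident, c("A", "B", "A", "B")), 0)
  expect_error(silhouette_score(pts, rep("A", 4)), "at least 2 clusters")
  expect_error(silhouette_score(pts[1:2, , drop = FALSE], c("A", "B")),
               "at least 3 points")
})

test_that("kmeans runner recovers separated blobs deterministically", {
  set.seed(12)
  blob <- rbind(matrix(rnorm(40, 0, 0.05), ncol = 2),
                matrix(rnorm(40, 5, 0.05), ncol = 2))
  rownames(blob) <- sprintf("p%02d", 1:40)
  truth <- rep(c("x", "y"), each = 20)
  run <- run_kmeans(blob, 2, seed = 4)
  agree <- max(mean((run$assignment == run$assignment[1]) == (truth == "x")),
               mean((run$assignment == run$assignment[1]) == (truth == "y")))
  expect_equal(agree, 1)
  expect_identical(run_kmeans(blob, 2, seed = 4)$assignment, run$assignment)

  one <- run_kmeans(blob, 1, seed = 1)
  expect_length(unique(one$assignment), 1)
  singletons <- run_kmeans(blob[1:5, ], 5, seed = 1)
  expect_length(unique(singletons$assignment), 5)
  expect_error(run_kmeans(blob, 41), "exceeds")
})

test_that("SOM runner captures blob structure and honors its contracts", {
  set.seed(13)
  blob <- rbind(matrix(rnorm(30, 0, 0.05), ncol = 2),
                matrix(rnorm(30, 5, 0.05), ncol = 2))
  rownames(blob) <- sprintf("q%02d", 1:30)
  truth <- rep(c("x", "y"), each = 15)
  run <- run_som(blob, grid_rows = 1, grid_cols = 2, epochs = 30, seed = 2)
  tab <- table(run$assignment, truth)
  expect_equal(sum(apply(tab, 1, max)), 30) # each unit owns one blob

  # epochs = 0: assignment by distance to the seeded initial weights only
  r0a <- run_som(blob, 1, 2, epochs = 0, seed = 5)
  r0b <- run_som(blob, 1, 2, epochs = 0, seed = 5)
  expect_identical(r0a$assignment, r0b$assignment)
  # untrained weights are exactly seeded sample rows of the data
  init_in_data <- apply(r0a$params$weights, 1, function(w) {
    any(apply(blob, 1, function(b) isTRUE(all.equal(unname(b), unname(w)))))
  })
  expect_true(all(init_in_data))
  ident <- matrix(1, nrow = 6, ncol = 3)
  rid <- run_som(ident, 1, 2, epochs = 5, seed = 1)
  expect_length(unique(rid$assignment), 1)
  expect_error(run_som(blob, 1, 1), "at least 2 units")
  expect_error(run_som(blob, 1, 2, learning_rate = 0), "positive")
})

test_that("evaluate_clustering emits a tidy deterministic results table", {
  spec <- synthetic_spec(ranks = "Domain", branching = 3,
                         species_per_leaf = 3, strains_per_species = 2,
                         drift = c(1.0, 0.05), total_units = 5000, seed = 21)
  ds <- generate_synthetic(spec)
  m <- frequency_matrix(ds)
  res <- evaluate_clustering(m, ds$taxonomy, methods = "kmeans",
                             k_range = 2:4, seed = 8)
  expect_named(res$results, c("method", "k", "silhouette", "tc_Domain"))
  expect_equal(nrow(res$results), 3)
  at3 <- res$results[res$results$k == 3, ]
  expect_lt(at3$tc_Domain, 0.1)
  expect_gt(at3$silhouette, 0.5)

  res2 <- evaluate_clustering(m, ds$taxonomy, methods = "kmeans",
                              k_range = 2:4, seed = 8)
  expect_identical(res$results, res2$results)
  expect_error(evaluate_clustering(m[1:5, ], ds$taxonomy, k_range = 2:8),
               "k_range")
})

test_that("supervised_report scores adapters and flags unseen labels", {
  oracle <- make_adapter(
    fit = function(x, y) list(key = y[order(x[, 1])], xs = sort(x[, 1])),
    predict = function(model, x) model$key[findInterval(x[, 1], model$xs)],
    name = "lookup")
  x <- matrix(1:6, ncol = 1)
  y <- c("a", "a", "b", "b", "c", "c")
  rep <- supervised_report(x, y, x, y, oracle)
  expect_equal(rep$accuracy, 1)
  expect_true(all(rep$confusion[upper.tri(rep$confusion)] == 0) &&
              all(rep$confusion[lower.tri(rep$confusion)] == 0))

  majority <- make_adapter(
    fit = function(x, y) names(which.max(table(y))),
    predict = function(model, x) rep(model, nrow(x)),
    name = "majority")
  test_y <- c(rep("big", 7), rep("small", 3))
  expect_warning(
    rep2 <- supervised_report(x, rep("big", 6), matrix(1:10, ncol = 1),
                              test_y, majority),
    "small")
  expect_equal(rep2$accuracy, 0.7)
  expect_warning(
    supervised_report(x, rep("big", 6), matrix(1:2, ncol = 1),
                      c("big", "never_seen"), majority),
    "never_seen")
})

test_that("logistic adapter separates synthetic clades on a blocked split", {
  spec <- synthetic_spec(ranks = "Domain", branching = 3,
                         species_per_leaf = 5, strains_per_species = 3,
                         drift = c(1.0, 0.1), total_units = 10000, seed = 33)
  ds <- generate_synthetic(spec)
  m <- frequency_matrix(ds)
  meta <- as.data.frame(ds$profiles)[, c("organism_id", "species", "Domain")]
  sp <- species_split(meta, stratify_rank = "Domain", seed = 5)
  labels <- labels_at_rank(ds$taxonomy, "Domain")
  std <- fit_standardizer(m[sp$train, ])
  rep <- supervised_report(
    apply_standardizer(std, m[sp$train, ]), labels[sp$train],
    apply_standardizer(std, m[sp$test, ]), labels[sp$test],
    adapter_logistic())
  expect_gt(rep$accuracy, 0.95)
  expect_equal(sum(rep$confusion), length(sp$test))
})
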