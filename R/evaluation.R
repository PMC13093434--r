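#' Species-blocked stratified train/test split
#'
#' Partitions organisms so that all strains of one species land wholly in
#' train or wholly in test (no leakage across the split), while the
#' species-level test fraction within each class of `stratify_rank`
#' approximates `test_fraction`. Allocation is greedy per stratum: species
#' are ordered largest-first (strain count, ties broken by a seeded
#' shuffle) and assigned to the test side while the stratum's test rows
#' remain below `test_fraction` of its rows. A stratum with a single
#' species goes entirely to train with a warning. The split is
#' deterministic given `seed` and is meant to be computed once and reused
#' across all target ranks.
#'
#' @param meta data.frame with one row per organism, containing
#'   `organism_id`, the species column and the stratification column.
#' @param test_fraction Fraction of rows per stratum targeted for test,
#'   in (0, 1). Default 0.2.
#' @param group_key Name of the species column. Default `"species"`.
#' @param stratify_rank Name of the column defining strata (a taxonomic
#'   rank). `NULL` treats all rows as one stratum.
#' @param seed Integer seed for tie-breaking.
#' @return List with `train` and `test` character vectors of organism_ids.
#' @export
species_split <- function(meta, test_fraction = 0.2, group_key = "species",
                          stratify_rank = NULL, seed = 1L) {
  meta <- as.data.frame(meta)
  if (!is.numeric(test_fraction) || test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)")
  }
  need <- c("organism_id", group_key, stratify_rank)
  missing <- setdiff(need, names(meta))
  if (length(missing)) stop("meta is missing column(s): ",
                            paste(missing, collapse = ", "))
  strata <- if (is.null(stratify_rank)) rep("<all>", nrow(meta)) else
    as.character(meta[[stratify_rank]])
  rng <- make_rng(seed)
  test_ids <- character(0)
  for (s in unique(strata)) {
    rows <- meta[strata == s, , drop = FALSE]
    sp_sizes <- table(rows[[group_key]])
    if (length(sp_sizes) < 2L) {
      warning("stratum '", s, "' has a single species; assigned to train",
              call. = FALSE)
      next
    }
    # largest-first, ties broken by seeded shuffle
    ord <- withr_rng(rng, function() sample(seq_along(sp_sizes)))
    sp <- names(sp_sizes)[ord][order(-as.integer(sp_sizes)[ord])]
    target <- test_fraction * nrow(rows)
    taken <- 0
    for (spec in sp) {
      if (taken >= target) break
      taken <- taken + sp_sizes[[spec]]
      test_ids <- c(test_ids, rows$organism_id[rows[[group_key]] == spec])
    }
  }
  train_ids <- setdiff(meta$organism_id, test_ids)
  # blocking invariant: no species straddles the split
  sp_train <- unique(meta[[group_key]][meta$organism_id %in% train_ids])
  sp_test <- unique(meta[[group_key]][meta$organism_id %in% test_ids])
  stopifnot(length(intersect(sp_train, sp_test)) == 0L)
  list(train = train_ids, test = test_ids)
}

# Local RNG helpers: evaluate `f` under a private seed without disturbing
# the caller's RNG state.
make_rng <- function(seed) {
  env <- new.env(parent = emptyenv())
  env$seed <- as.integer(seed)
  env
}

withr_rng <- function(rng, f) {
  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit({
    if (is.null(old)) rm(".Random.seed", envir = globalenv()) else
      assign(".Random.seed", old, envir = globalenv())
  })
  set.seed(rng$seed)
  out <- f()
  rng$seed <- rng$seed + 1L
  out
}

#' Train-only feature standardization
#'
#' Fits per-feature mean and standard deviation on training rows only and
#' applies the same affine map `(x - mean) / sd` to any rows, preventing
#' test-set leakage into the feature scaling. Constant features (sd = 0)
#' are mapped to zero (sd treated as 1) with a warning -- common for
#' all-zero codon-pair columns on small data.
#'
#' @param x Numeric matrix of training rows (organisms x features).
#' @return An object of class `standardizer` with `mean`, `sd` and
#'   `constant` (logical per feature).
#' @export
fit_standardizer <- function(x) {
  x <- as.matrix(x)
  if (nrow(x) < 2L) stop("need at least 2 training rows to standardize")
  mu <- colMeans(x)
  sdv <- apply(x, 2L, stats::sd)
  constant <- sdv == 0 | is.na(sdv)
  if (any(constant)) {
    warning(sum(constant), " constant feature(s) standardized to zero",
            call. = FALSE)
    sdv[constant] <- 1
  }
  structure(list(mean = mu, sd = sdv, constant = constant),
            class = "standardizer")
}

#' @rdname fit_standardizer
#' @param model A fitted `standardizer`.
#' @param newx Numeric matrix to transform with the training statistics.
#' @return `apply_standardizer`: the transformed matrix.
#' @export
apply_standardizer <- function(model, newx) {
  stopifnot(inherits(model, "standardizer"))
  newx <- as.matrix(newx)
  if (ncol(newx) != length(model$mean)) stop("feature dimension mismatch")
  sweep(sweep(newx, 2L, model$mean, "-"), 2L, model$sd, "/")
}

#' Mean Silhouette coefficient
#'
#' Average over points of `(b - a) / max(a, b)` with `a` the mean Euclidean
#' distance to the point's own cluster (excluding itself) and `b` the
#' smallest mean distance to any other cluster. Points in singleton
#' clusters score 0. Ranges over \[-1, 1\]; higher means more cohesive,
#' better-separated clusters.
#'
#' @param points Numeric matrix (n x d), n >= 3.
#' @param labels Cluster labels, length n, at least 2 distinct values.
#' @return Mean silhouette width.
#' @export
silhouette_score <- function(points, labels) {
  points <- as.matrix(points)
  n <- nrow(points)
  if (n < 3L) stop("need at least 3 points for a silhouette score")
  if (length(labels) != n) stop("labels must match the number of rows")
  cl <- as.integer(factor(labels))
  if (length(unique(cl)) < 2L) stop("silhouette requires at least 2 clusters")
  sil <- cluster::silhouette(cl, stats::dist(points))
  mean(sil[, "sil_width"])
}

clustering_run <- function(method, k, seed, assignment, params = list()) {
  structure(list(method = method, k = k, seed = seed,
                 assignment = assignment, params = params),
            class = "clustering_run")
}

#' @export
print.clustering_run <- function(x, ...) {
  cat(sprintf("<clustering_run> %s, k = %d, seed = %d: %d point(s), %d non-empty cluster(s)\n",
              x$method, x$k, x$seed, length(x$assignment),
              length(unique(x$assignment))))
  invisible(x)
}

#' K-means clustering runner
#'
#' Seeded wrapper around Lloyd-style K-means ([stats::kmeans()], Hartigan-
#' Wong) returning a labelled assignment keyed by the matrix rownames.
#' Deterministic given `seed`; within-cluster sum of squares of the fit is
#' kept in `params$inertia`.
#'
#' @param points Numeric matrix (n x d) with organism rownames.
#' @param k Number of clusters, 1 <= k <= n.
#' @param seed Integer seed.
#' @param n_init Number of random restarts. Default 10.
#' @param max_iter Iteration cap. Default 100.
#' @return A `clustering_run` with `assignment` = named character vector of
#'   cluster labels `"1"`..`"k"`.
#' @export
run_kmeans <- function(points, k, seed = 1L, n_init = 10L, max_iter = 100L) {
  points <- as.matrix(points)
  if (k > nrow(points)) stop("k = ", k, " exceeds the number of points")
  if (k < 1L) stop("k must be >= 1")
  rng <- make_rng(seed)
  fit <- withr_rng(rng, function() {
    if (k == 1L) {
      list(cluster = rep(1L, nrow(points)),
           tot.withinss = sum(scale(points, scale = FALSE)^2))
    } else if (k == nrow(points)) {
      # every point its own cluster; stats::kmeans rejects this boundary
      list(cluster = seq_len(nrow(points)), tot.withinss = 0)
    } else {
      stats::kmeans(points, centers = k, nstart = n_init,
                    iter.max = max_iter)
    }
  })
  ids <- rownames(points)
  if (is.null(ids)) ids <- as.character(seq_len(nrow(points)))
  clustering_run("kmeans", as.integer(k), as.integer(seed),
                 stats::setNames(as.character(fit$cluster), ids),
                 params = list(inertia = fit$tot.withinss,
                               n_init = n_init, max_iter = max_iter))
}

#' Self-organizing-map clustering runner
#'
#' Minimal online SOM on a `grid_rows` x `grid_cols` lattice. Unit weights
#' are initialized from data rows (seeded sample). Each epoch presents the
#' samples in a fresh seeded order; for each sample the best-matching unit
#' (BMU, smallest Euclidean distance) and its lattice neighbours are pulled
#' toward the sample, `w_u <- w_u + eta(t) * h(u, bmu, sigma(t)) * (x - w_u)`,
#' with Gaussian neighbourhood `h = exp(-d_grid^2 / (2 sigma(t)^2))` and
#' learning rate / radius decaying linearly over the total steps (to 1% of
#' their initial values). Cluster label = BMU index after training, so a
#' 1 x k grid is directly comparable to K-means with k clusters. With
#' `epochs = 0` points are mapped onto the initial (seeded) weights.
#'
#' @param points Numeric matrix (n x d) with organism rownames.
#' @param grid_rows,grid_cols Lattice dimensions; their product (>= 2) is
#'   the number of available clusters.
#' @param learning_rate Initial eta > 0. Default 0.5.
#' @param sigma Initial neighbourhood radius > 0 in lattice units;
#'   default half the larger grid dimension.
#' @param epochs Training passes over the data. Default 20.
#' @param seed Integer seed (initialization + presentation order).
#' @return A `clustering_run` with unit labels `"1"`..`"grid_rows*grid_cols"`.
#' @export
run_som <- function(points, grid_rows = 1L, grid_cols = 2L,
                    learning_rate = 0.5, sigma = NULL, epochs = 20L,
                    seed = 1L) {
  points <- as.matrix(points)
  n_units <- grid_rows * grid_cols
  if (n_units < 2L) stop("SOM grid must have at least 2 units")
  if (learning_rate <= 0) stop("learning_rate must be positive")
  if (is.null(sigma)) sigma <- max(grid_rows, grid_cols) / 2
  if (sigma <= 0) stop("sigma must be positive")
  n <- nrow(points)
  grid <- cbind(row = rep(seq_len(grid_rows), times = grid_cols),
                col = rep(seq_len(grid_cols), each = grid_rows))
  grid_d2 <- as.matrix(stats::dist(grid))^2
  rng <- make_rng(seed)
  w <- withr_rng(rng, function() {
    points[sample(n, n_units, replace = n_units > n), , drop = FALSE]
  })
  bmu_of <- function(x) which.min(colSums((t(w) - x)^2))
  total_steps <- max(epochs * n, 1L)
  step <- 0L
  for (ep in seq_len(epochs)) {
    order_ep <- withr_rng(rng, function() sample(n))
    for (i in order_ep) {
      frac <- step / total_steps
      eta <- learning_rate * (1 - 0.99 * frac)
      sig <- sigma * (1 - 0.99 * frac)
      x <- points[i, ]
      bmu <- bmu_of(x)
      h <- exp(-grid_d2[bmu, ] / (2 * sig^2))
      w <- w + (eta * h) * sweep(-w, 2L, x, "+")
      step <- step + 1L
    }
  }
  assign <- apply(points, 1L, bmu_of)
  ids <- rownames(points)
  if (is.null(ids)) ids <- as.character(seq_len(n))
  clustering_run("som", as.integer(n_units), as.integer(seed),
                 stats::setNames(as.character(assign), ids),
                 params = list(grid = c(grid_rows, grid_cols),
                               learning_rate = learning_rate, sigma = sigma,
                               epochs = epochs, weights = w))
}

#' Run and score clusterings over a range of K
#'
#' For each method and each K in `k_range`, fits the clustering on the
#' feature matrix, computes the Silhouette coefficient (internal validity,
#' feature space only) and the Taxonomic Consistency at each requested rank
#' (external validity against the reference taxonomy). SOM uses a 1 x K
#' lattice so K is comparable across methods.
#'
#' @param points Numeric matrix (n x d) with organism rownames matching the
#'   taxonomy.
#' @param taxonomy A [taxonomy_table] covering the rows.
#' @param ranks Ranks at which to compute TC (default: all in `taxonomy`).
#' @param methods Subset of `c("kmeans", "som")`.
#' @param k_range Integer vector of cluster counts, all within \[2, n - 1\].
#' @param seed Integer seed.
#' @param som_epochs Training epochs for the SOM runs. Default 20.
#' @return A list: `results` -- tidy data.frame with columns `method`, `k`,
#'   `silhouette` and one `tc_<rank>` column per rank -- and `runs`, the
#'   underlying `clustering_run` objects.
#' @export
evaluate_clustering <- function(points, taxonomy,
                                ranks = attr(taxonomy, "ranks"),
                                methods = c("kmeans", "som"),
                                k_range = 2:8, seed = 1L, som_epochs = 20L) {
  points <- as.matrix(points)
  methods <- match.arg(methods, several.ok = TRUE)
  n <- nrow(points)
  if (any(k_range < 2L) || any(k_range > n - 1L)) {
    stop("k_range must lie within [2, n - 1] = [2, ", n - 1L, "]")
  }
  runs <- list()
  rows <- list()
  for (method in methods) {
    for (k in k_range) {
      run <- if (method == "kmeans") {
        run_kmeans(points, k, seed = seed)
      } else {
        run_som(points, grid_rows = 1L, grid_cols = k, epochs = som_epochs,
                seed = seed)
      }
      sil <- silhouette_score(points, run$assignment)
      tcs <- vapply(ranks, function(r) {
        tc_score(run$assignment, taxonomy, r)$tc
      }, numeric(1))
      row <- data.frame(method = method, k = as.integer(k),
                        silhouette = sil, stringsAsFactors = FALSE)
      row[paste0("tc_", ranks)] <- as.list(tcs)
      rows[[length(rows) + 1L]] <- row
      runs[[paste(method, k, sep = "_")]] <- run
    }
  }
  list(results = do.call(rbind, rows), runs = runs)
}

#' Classifier adapters
#'
#' The supervised harness is classifier-agnostic: any object exposing
#' `fit(x, y)` returning a fitted model and `predict(model, x)` returning a
#' character vector of labels plugs in. `make_adapter()` builds one from
#' two functions; the ready-made adapters wrap multinomial logistic
#' regression (`nnet::multinom`), and -- when the corresponding package is
#' installed -- a random forest, an SVM and a decision tree.
#'
#' @param fit Function `(x, y) -> model` (x numeric matrix, y character).
#' @param predict Function `(model, x) -> character vector`.
#' @param name Adapter label used in reports.
#' @return A list of class `classifier_adapter`.
#' @export
make_adapter <- function(fit, predict, name = "custom") {
  stopifnot(is.function(fit), is.function(predict))
  structure(list(fit = fit, predict = predict, name = name),
            class = "classifier_adapter")
}

#' @rdname make_adapter
#' @param max_iter Optimizer iteration cap for the logistic adapter.
#' @export
adapter_logistic <- function(max_iter = 200L) {
  make_adapter(
    fit = function(x, y) {
      df <- as.data.frame(x)
      df$.y <- factor(y)
      nnet::multinom(.y ~ ., data = df, trace = FALSE, maxit = max_iter,
                     MaxNWts = (ncol(x) + 1L) * nlevels(df$.y) + 10L)
    },
    predict = function(model, x) {
      as.character(stats::predict(model, newdata = as.data.frame(x),
                                  type = "class"))
    },
    name = "logistic"
  )
}

#' @rdname make_adapter
#' @param ntree Number of trees for the random-forest adapter.
#' @export
adapter_random_forest <- function(ntree = 200L) {
  if (!requireNamespace("randomForest", quietly = TRUE)) {
    stop("adapter_random_forest requires the 'randomForest' package")
  }
  make_adapter(
    fit = function(x, y) randomForest::randomForest(x, factor(y), ntree = ntree),
    predict = function(model, x) as.character(stats::predict(model, x)),
    name = "random_forest"
  )
}

#' @rdname make_adapter
#' @export
adapter_svm <- function() {
  if (!requireNamespace("e1071", quietly = TRUE)) {
    stop("adapter_svm requires the 'e1071' package")
  }
  make_adapter(
    fit = function(x, y) e1071::svm(x, factor(y)),
    predict = function(model, x) as.character(stats::predict(model, x)),
    name = "svm"
  )
}

#' @rdname make_adapter
#' @export
adapter_tree <- function() {
  if (!requireNamespace("rpart", quietly = TRUE)) {
    stop("adapter_tree requires the 'rpart' package")
  }
  make_adapter(
    fit = function(x, y) {
      df <- as.data.frame(x)
      df$.y <- factor(y)
      rpart::rpart(.y ~ ., data = df, method = "class")
    },
    predict = function(model, x) {
      as.character(stats::predict(model, newdata = as.data.frame(x),
                                  type = "class"))
    },
    name = "tree"
  )
}

#' Supervised accuracy and confusion matrix
#'
#' Fits the adapter on the training partition and reports test accuracy
#' (correct / total) and the confusion matrix (rows = true labels, columns
#' = predicted labels, label order = sorted union, emitted as dimnames).
#' Test labels never seen in training cannot be predicted; they stay in the
#' matrix as all-miss rows and trigger a warning.
#'
#' @param train_x,test_x Numeric feature matrices.
#' @param train_y,test_y Character label vectors.
#' @param adapter A [make_adapter()] object.
#' @return List of class `supervised_report`: `accuracy`, `confusion`
#'   (matrix), `labels`, `adapter` (name), `n_train`, `n_test`.
#' @export
supervised_report <- function(train_x, train_y, test_x, test_y, adapter) {
  stopifnot(inherits(adapter, "classifier_adapter"))
  train_y <- as.character(train_y)
  test_y <- as.character(test_y)
  unseen <- setdiff(unique(test_y), unique(train_y))
  if (length(unseen)) {
    warning("test label(s) absent from training (counted as errors): ",
            paste(unseen, collapse = ", "), call. = FALSE)
  }
  model <- adapter$fit(as.matrix(train_x), train_y)
  pred <- as.character(adapter$predict(model, as.matrix(test_x)))
  labels <- sort(unique(c(train_y, test_y, pred)))
  confusion <- table(factor(test_y, levels = labels),
                     factor(pred, levels = labels))
  confusion <- unclass(confusion)
  names(dimnames(confusion)) <- c("true", "predicted")
  structure(list(accuracy = mean(pred == test_y), confusion = confusion,
                 labels = labels, adapter = adapter$name,
                 n_train = length(train_y), n_test = length(test_y)),
            class = "supervised_report")
}

#' @export
print.supervised_report <- function(x, ...) {
  cat(sprintf("<supervised_report> %s: accuracy %.3f (train n = %d, test n = %d)\n",
              x$adapter, x$accuracy, x$n_train, x$n_test))
  print(x$confusion)
  invisible(x)
}
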