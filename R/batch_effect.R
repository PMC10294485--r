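# Diagnosing whether learned slide representations separate biological
# classes or datasets of origin. The quantitative tool is k-NN label
# purity on the original features; the 2-D embedding is a reporting
# convenience only.

#' Pooled slide features under a model
#'
#' For each slide: the mean over its bags of the bag-level pooled feature
#' (the same mean pooling used before the head in [forward_bag()], taken
#' pre-head). Deterministic given the bag seed.
#'
#' @param model a `mil_model`.
#' @param manifest slide manifest with `store_path` filled in.
#' @param config configuration (defaults to the model's).
#' @param seed bag-sampling seed.
#' @param feature_cache optional environment of per-slide feature tables
#'   (shared with protocol runs using the same backbone).
#' @return A `feature_table`: list with `features` (n x D matrix, one row
#'   per slide) and `manifest` (rows aligned with the features; slides with
#'   empty stores are skipped with a warning).
#' @export
extract_pooled_features <- function(model, manifest, config = model$config,
                                    seed = 1L, feature_cache = NULL) {
  store_fn <- manifest_store_fn(manifest)
  cache <- feature_cache %||% new.env(parent = emptyenv())
  rows <- list(); feats <- list()
  for (i in seq_len(nrow(manifest))) {
    s <- manifest$slide_id[i]
    Z <- features_for_slide(cache, s, model$backbone, config, store_fn,
                            variants = "00")[["00"]]
    if (ncol(Z) == 0L) {
      warning("slide ", s, " has an empty tile store; skipped")
      next
    }
    bag_idx <- with_seed(derive_seed(seed, s), sample_bag_indices(ncol(Z), config))
    pooled <- vapply(bag_idx, function(idx) {
      bag_forward_z(model$params, Z[, idx, drop = FALSE])$pooled
    }, numeric(model$config$feature_dim))
    feats[[length(feats) + 1L]] <- rowMeans(matrix(pooled, nrow = model$config$feature_dim))
    rows[[length(rows) + 1L]] <- manifest[i, , drop = FALSE]
  }
  structure(
    list(features = do.call(rbind, feats), manifest = do.call(rbind, rows)),
    class = "feature_table"
  )
}

#' k-nearest-neighbor label purity
#'
#' For each row, the fraction of its k nearest neighbors (Euclidean,
#' self excluded, distance ties broken by row order) sharing its label;
#' purity is the mean over rows. Random labels give purity near the largest
#' class share; well-separated label-aligned clusters give purity near 1.
#'
#' @param features n x D numeric matrix.
#' @param labels length-n vector of labels.
#' @param k neighbor count (default 10; must be < n).
#' @return Mean purity in \[0, 1\]. Constant labels return 1 with a warning.
#' @export
knn_label_purity <- function(features, labels, k = 10L) {
  n <- nrow(features)
  if (n <= k) abort_wsimil("need more rows than neighbors", "wsimil_parameter_error")
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) {
    warning("labels are constant; purity is trivially 1")
    return(1.0)
  }
  D <- as.matrix(stats::dist(features))
  diag(D) <- Inf
  mean(vapply(seq_len(n), function(i) {
    nb <- order(D[i, ])[seq_len(k)]  # order() breaks ties by row index
    mean(labels[nb] == labels[i])
  }, numeric(1L)))
}

# Symmetrized kNN adjacency of a feature matrix.
knn_graph <- function(features, k) {
  n <- nrow(features)
  D <- as.matrix(stats::dist(features))
  diag(D) <- Inf
  A <- matrix(0, n, n)
  for (i in seq_len(n)) A[i, order(D[i, ])[seq_len(k)]] <- 1
  pmax(A, t(A))
}

#' Neighbor-graph 2-D embedding of a feature table
#'
#' Laplacian-eigenmap embedding of the symmetrized k-nearest-neighbor
#' graph: coordinates are the eigenvectors of the symmetric normalized
#' graph Laplacian belonging to the two smallest non-trivial eigenvalues
#' (eigenvector signs fixed by convention, so the output is deterministic;
#' `seed` is accepted for interface symmetry but no randomness is
#' involved). For reporting only — quantitative claims use
#' [knn_label_purity()] on the original features.
#'
#' @param features n x D numeric matrix, n >= 10.
#' @param seed unused (deterministic method).
#' @param k neighbor count of the graph.
#' @return n x 2 matrix of finite coordinates.
#' @export
embed_2d <- function(features, seed = 1L, k = 10L) {
  n <- nrow(features)
  if (n < 10L) {
    abort_wsimil("too few rows to embed (n < 10); use knn_label_purity alone",
                 "wsimil_parameter_error")
  }
  k <- min(k, n - 1L)
  A <- knn_graph(features, k)
  d <- pmax(rowSums(A), 1e-12)
  Dm <- 1 / sqrt(d)
  L <- diag(n) - (Dm %o% Dm) * A
  eig <- eigen((L + t(L)) / 2, symmetric = TRUE)
  ord <- order(eig$values)
  # skip exactly one trivial (constant) eigenvector; with a disconnected
  # graph the remaining zero-eigenvalue vectors encode component
  # membership, which is structure worth plotting
  idx <- ord[2:3]
  coords <- eig$vectors[, idx, drop = FALSE] * Dm
  # deterministic sign: largest-magnitude entry of each axis is positive
  for (j in 1:2) {
    m <- which.max(abs(coords[, j]))
    if (coords[m, j] < 0) coords[, j] <- -coords[, j]
  }
  colnames(coords) <- c("dim1", "dim2")
  coords
}

#' Class-vs-dataset separation report
#'
#' Quantifies the batch-effect diagnosis: `purity_dataset` and
#' `purity_class` are k-NN label purities of the slide features under the
#' dataset-of-origin and class labels; their difference, the
#' `confounding_index`, is positive when neighborhoods are organized by
#' dataset more than by class. Note the index has a structural ceiling of
#' roughly twice the class/dataset label-disagreement rate of the evaluated
#' slides: when class and dataset labels nearly coincide (heavily
#' confounded collections), both purities move together and the index
#' stays close to zero even for features that encode only the dataset.
#'
#' @param table a `feature_table` from [extract_pooled_features()].
#' @param k neighbor count.
#' @param seed passed to [embed_2d()].
#' @param embed also compute the 2-D embedding (requires n >= 10).
#' @return A `separation_report`: `k`, `purity_class`, `purity_dataset`,
#'   `confounding_index`, and `embedding_2d` (or NULL).
#' @export
separation_report <- function(table, k = 10L, seed = 1L, embed = TRUE) {
  pc <- knn_label_purity(table$features, table$manifest$class_label, k)
  pd <- knn_label_purity(table$features, table$manifest$dataset_id, k)
  emb <- if (embed && nrow(table$features) >= 10L) {
    embed_2d(table$features, seed = seed, k = k)
  } else {
    NULL
  }
  structure(
    list(k = as.integer(k), purity_class = pc, purity_dataset = pd,
         confounding_index = pd - pc, embedding_2d = emb),
    class = "separation_report"
  )
}
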