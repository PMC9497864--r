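# Compound correlation among drying conditions: standardized feature
# matrix, PCA loadings, and Ward hierarchical clustering with a fixed
# cluster count.

#' Standardized feature matrix of drying conditions
#'
#' Selects numeric feature columns, centres each to mean zero and scales
#' to unit population variance (divisor `n`, so two samples standardize
#' to exactly +/-1). A zero-variance column cannot be standardized and is
#' reported by name.
#'
#' @param samples Data frame, one row per drying condition.
#' @param columns Character vector of feature columns to use.
#' @return Numeric matrix (rows named by `samples$run_id` or `samples$sr`
#'   when present).
#' @export
feature_matrix <- function(samples, columns) {
  stopifnot(is.data.frame(samples))
  if (nrow(samples) < 2L) abort("need at least two samples.")
  missing_cols <- setdiff(columns, names(samples))
  if (length(missing_cols) > 0L) {
    abort(sprintf("missing feature columns: %s", paste(missing_cols, collapse = ", ")))
  }
  mat <- as.matrix(samples[, columns, drop = FALSE])
  if (!is.numeric(mat)) abort("feature columns must be numeric.")
  if (anyNA(mat)) abort("feature columns must not contain missing values.")
  vars <- apply(mat, 2, var)
  if (any(vars == 0)) {
    abort(sprintf(
      "zero-variance feature column(s): %s",
      paste(columns[vars == 0], collapse = ", ")
    ))
  }
  n <- nrow(mat)
  pop_sd <- sqrt(vars * (n - 1) / n)
  out <- scale(mat, center = TRUE, scale = pop_sd)
  attr(out, "scaled:center") <- NULL
  attr(out, "scaled:scale") <- NULL
  rownames(out) <- if ("run_id" %in% names(samples)) {
    as.character(samples$run_id)
  } else if ("sr" %in% names(samples)) {
    as.character(samples$sr)
  } else {
    as.character(seq_len(nrow(samples)))
  }
  out
}

#' Loadings of the first two principal components
#'
#' PCA of an already-standardized matrix (no further scaling). Loading
#' signs are fixed so the largest-magnitude loading of each component is
#' positive, making the output deterministic across BLAS builds.
#'
#' @param mat Numeric matrix from [feature_matrix()], at least 3 rows.
#' @return List: `loadings` (columns PC1, PC2), `explained_variance`
#'   (proportion per component, all components), `degenerate` (logical
#'   per component: near-zero variance).
#' @export
pca_loadings <- function(mat) {
  if (nrow(mat) < 3L) abort("need at least three rows for PCA.")
  p <- prcomp(mat, center = FALSE, scale. = FALSE)
  expl <- p$sdev^2 / sum(p$sdev^2)
  rot <- p$rotation
  for (j in seq_len(ncol(rot))) {
    i_max <- which.max(abs(rot[, j]))
    if (rot[i_max, j] < 0) rot[, j] <- -rot[, j]
  }
  list(
    loadings = rot[, 1:2, drop = FALSE],
    explained_variance = expl,
    degenerate = p$sdev^2 < 1e-12
  )
}

#' Ward hierarchical clustering of drying conditions
#'
#' Agglomerative clustering (Ward linkage on Euclidean distances) of the
#' standardized feature matrix, cut at `n_clusters`. Labels are
#' renumbered in order of first appearance so they are invariant to row
#' permutation up to relabeling.
#'
#' @param mat Numeric matrix from [feature_matrix()].
#' @param n_clusters Number of groups (default 4).
#' @return List: `labels` (integer per row), `tree` (the `hclust`
#'   object), `heights` (merge heights).
#' @export
cluster_samples <- function(mat, n_clusters = 4) {
  if (n_clusters > nrow(mat)) {
    abort("`n_clusters` cannot exceed the number of rows.")
  }
  tree <- hclust(dist(mat), method = "ward.D2")
  raw <- cutree(tree, k = n_clusters)
  labels <- match(raw, unique(raw))
  list(labels = labels, tree = tree, heights = tree$height)
}

#' Agreement between two clusterings
#'
#' Adjusted Rand index between two label vectors: 1 for identical
#' partitions (up to relabeling), ~0 for random agreement.
#'
#' @param labels,reference Integer label vectors of equal length.
#' @return Adjusted Rand index.
#' @export
cluster_agreement <- function(labels, reference) {
  if (length(labels) != length(reference)) abort("label lengths differ.")
  mclust::adjustedRandIndex(labels, reference)
}
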