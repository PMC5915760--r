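#' Principal component analysis of samples
#'
#' PCA by singular value decomposition on the complete log2 matrix, with
#' samples as observations and proteins as variables (column-centred, not
#' scaled; z-scoring is a separate explicit step). Component signs are fixed
#' by requiring the largest-magnitude loading of each component to be
#' positive, so results are fully deterministic.
#'
#' @param x a complete `expr_matrix`.
#' @param center centre protein columns before the SVD (default TRUE).
#' @return Object of class `lfq_pca` with `scores` (samples x components),
#'   `loadings` (proteins x components) and `explained_variance` fractions.
#' @export
lfq_pca <- function(x, center = TRUE) {
  if (!is_complete(x)) {
    abort("matrix has missing values; run impute_downshift() first",
          class = "progmarker_validation_error")
  }
  if (ncol(x$values) < 2) {
    abort("need at least 2 samples", class = "progmarker_validation_error")
  }
  fit <- prcomp(t(x$values), center = center, scale. = FALSE)
  flip <- vapply(seq_len(ncol(fit$rotation)), function(k) {
    w <- fit$rotation[, k]
    sign(w[which.max(abs(w))])
  }, 0)
  flip[flip == 0] <- 1
  scores <- sweep(fit$x, 2, flip, `*`)
  loadings <- sweep(fit$rotation, 2, flip, `*`)
  ev <- fit$sdev^2 / sum(fit$sdev^2)
  structure(
    list(scores = scores, loadings = loadings, explained_variance = ev,
         samples = sample_names(x), center = center),
    class = "lfq_pca"
  )
}

#' @export
print.lfq_pca <- function(x, ...) {
  cat(sprintf("<lfq_pca> %d samples, %d components; PC1 %.1f%%, PC2 %.1f%%\n",
              nrow(x$scores), ncol(x$scores),
              100 * x$explained_variance[1],
              100 * x$explained_variance[2] %||% NA))
  invisible(x)
}

#' @export
tidy.lfq_pca <- function(x, ...) {
  scores <- as.data.frame(x$scores)
  out <- tibble(sample = x$samples)
  for (nm in names(scores)) out[[nm]] <- scores[[nm]]
  out
}

#' @export
glance.lfq_pca <- function(x, ...) {
  tibble(
    n_samples = nrow(x$scores),
    n_components = ncol(x$scores),
    pc1_variance = x$explained_variance[1],
    pc2_variance = if (length(x$explained_variance) > 1)
      x$explained_variance[2] else NA_real_
  )
}

#' Hierarchical clustering under Euclidean distance
#'
#' Agglomerative clustering of samples or proteins on the (typically
#' z-scored) log2 matrix, Euclidean distance, configurable linkage (average
#' linkage by default, the Perseus convention).
#'
#' @param x a complete `expr_matrix`; apply [zscore_rows()] first to match
#'   the usual heatmap normalisation.
#' @param axis cluster `"samples"` (default) or `"proteins"`.
#' @param linkage one of `"average"`, `"single"`, `"complete"`, `"ward"`.
#' @return Object of class `lfq_hclust` wrapping the `stats::hclust` tree.
#' @export
hierarchical_cluster <- function(x, axis = c("samples", "proteins"),
                                 linkage = c("average", "single",
                                             "complete", "ward")) {
  axis <- match.arg(axis)
  linkage <- match.arg(linkage)
  if (!is_complete(x)) {
    abort("matrix has missing values; run impute_downshift() first",
          class = "progmarker_validation_error")
  }
  m <- if (axis == "samples") t(x$values) else x$values
  if (axis == "proteins") rownames(m) <- x$proteins$protein_ids
  if (nrow(m) < 2) {
    abort("need at least 2 items to cluster",
          class = "progmarker_validation_error")
  }
  method <- if (linkage == "ward") "ward.D2" else linkage
  tree <- hclust(dist(m, method = "euclidean"), method = method)
  structure(
    list(tree = tree, axis = axis, linkage = linkage, labels = rownames(m)),
    class = "lfq_hclust"
  )
}

#' @export
print.lfq_hclust <- function(x, ...) {
  cat(sprintf("<lfq_hclust> %d %s, %s linkage, Euclidean distance\n",
              length(x$labels), x$axis, x$linkage))
  invisible(x)
}

#' Merge table of a clustering tree
#'
#' @param x an `lfq_hclust`.
#' @param ... unused.
#' @return Tibble with one row per agglomeration step: `step`, `height`, and
#'   the merged node indices in `stats::hclust` convention.
#' @export
tidy.lfq_hclust <- function(x, ...) {
  tibble(
    step = seq_len(nrow(x$tree$merge)),
    left = x$tree$merge[, 1],
    right = x$tree$merge[, 2],
    height = x$tree$height
  )
}

#' Cut a clustering tree into k groups
#'
#' @param clustering an `lfq_hclust`.
#' @param k number of clusters, between 1 and the item count.
#' @return Tibble with `item` and `cluster` (integer assignment).
#' @export
cut_clusters <- function(clustering, k) {
  n <- length(clustering$labels)
  if (k < 1 || k > n) {
    abort(sprintf("k must be between 1 and %d", n),
          class = "progmarker_validation_error")
  }
  assignment <- cutree(clustering$tree, k = k)
  tibble(item = clustering$labels, cluster = unname(assignment))
}

#' Agreement between a clustering and external labels
#'
#' Adjusted Rand index between a cluster assignment and a labelling of the
#' same items: 1 for identical partitions, about 0 for chance-level
#' agreement.
#'
#' @param assignments integer/character cluster per item (or the tibble from
#'   [cut_clusters()]).
#' @param labels external label per item, same order/length.
#' @return The adjusted Rand index, a single number in `[-1, 1]`.
#' @export
label_agreement <- function(assignments, labels) {
  if (is.data.frame(assignments)) assignments <- assignments$cluster
  if (length(assignments) != length(labels)) {
    abort("assignments and labels must have the same length",
          class = "progmarker_validation_error")
  }
  mclust::adjustedRandIndex(assignments, labels)
}
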