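# Unsupervised structure: agglomerative clustering of samples with
# Davies-Bouldin model selection, a cluster-diagnosis association test, and
# PCA on the significant-probe submatrix. Matrix convention in this file:
# samples in rows, features (probes) in columns, as for stats::prcomp.

#' Samples-by-features view of a beta matrix
#'
#' @param m A [beta_matrix()].
#' @param probes Optional probe subset (e.g. significant probes).
#' @return A samples x probes numeric matrix.
#' @export
samples_matrix <- function(m, probes = NULL) {
  stopifnot(inherits(m, "beta_matrix"))
  v <- if (is.null(probes)) m$values else m$values[probes, , drop = FALSE]
  t(v)
}

#' Agglomerative hierarchical clustering of samples
#'
#' @param x Samples x features numeric matrix (no missing values).
#' @param linkage Agglomeration method for [stats::hclust()] (default
#'   `"average"`).
#' @param metric Distance metric for [stats::dist()] (default
#'   `"euclidean"`).
#' @return An `hclust` merge tree.
#' @export
hierarchical_cluster <- function(x, linkage = "average", metric = "euclidean") {
  stopifnot(is.matrix(x), nrow(x) >= 2)
  if (anyNA(x)) stop("missing values in clustering input", call. = FALSE)
  stats::hclust(stats::dist(x, method = metric), method = linkage)
}

#' Davies-Bouldin index
#'
#' `DB = (1/k) * sum_i max_{j != i} (S_i + S_j) / d(c_i, c_j)` where `S_i`
#' is the mean Euclidean distance of cluster members to their centroid
#' `c_i`. Lower is better; 0 for perfectly tight clusters.
#'
#' @param x Samples x features numeric matrix.
#' @param labels Cluster assignment per sample (>= 2 nonempty clusters).
#' @return The index (a scalar).
#' @export
davies_bouldin <- function(x, labels) {
  stopifnot(is.matrix(x), length(labels) == nrow(x))
  labels <- as.character(labels)
  levs <- unique(labels)
  k <- length(levs)
  if (k < 2) stop("need >= 2 clusters", call. = FALSE)
  cent <- do.call(rbind, lapply(levs, function(l) {
    colMeans(x[labels == l, , drop = FALSE])
  }))
  scat <- vapply(seq_len(k), function(i) {
    xi <- x[labels == levs[i], , drop = FALSE]
    mean(sqrt(rowSums(sweep(xi, 2, cent[i, ], `-`)^2)))
  }, numeric(1))
  cd <- as.matrix(stats::dist(cent))
  if (any(cd[upper.tri(cd)] <= .Machine$double.eps)) {
    stop("coincident cluster centroids: index undefined", call. = FALSE)
  }
  r <- vapply(seq_len(k), function(i) {
    max((scat[i] + scat[-i]) / cd[i, -i])
  }, numeric(1))
  mean(r)
}

#' Cut a tree at candidate k and select by Davies-Bouldin
#'
#' Cuts the merge tree at every k in `k_range`, scores each partition with
#' the Davies-Bouldin index, and selects the minimiser (ties broken toward
#' the smaller k). A warning is raised when the index curve is flat within
#' 1% of its range, indicating no real cluster structure.
#'
#' @param tree An `hclust` tree (from [hierarchical_cluster()]).
#' @param x The samples x features matrix the tree was built on.
#' @param k_range Candidate cluster counts, within \[2, n - 1\].
#' @return A `clustering_result`: list with `tree`, `db_by_k` (tibble `k`,
#'   `db`), `k_star`, and `labels` (named integer vector, a partition into
#'   `k_star` nonempty clusters).
#' @export
select_k_and_label <- function(tree, x, k_range = 2:6) {
  stopifnot(inherits(tree, "hclust"))
  if (length(k_range) == 0) stop("empty k_range", call. = FALSE)
  n <- nrow(x)
  k_range <- sort(unique(as.integer(k_range)))
  if (any(k_range < 2 | k_range > n - 1)) {
    stop("k_range must lie within [2, n - 1]", call. = FALSE)
  }
  db <- vapply(k_range, function(k) {
    davies_bouldin(x, stats::cutree(tree, k = k))
  }, numeric(1))
  k_star <- k_range[which.min(db)]
  rng <- diff(range(db))
  if (rng <= 0.01 * max(abs(db))) {
    warning("Davies-Bouldin curve flat within 1%; no clear cluster structure",
      call. = FALSE
    )
  }
  labels <- stats::cutree(tree, k = k_star)
  structure(
    list(
      tree = tree,
      db_by_k = tibble::tibble(k = k_range, db = db),
      k_star = k_star,
      labels = labels
    ),
    class = "clustering_result"
  )
}

#' @export
print.clustering_result <- function(x, ...) {
  cat(sprintf(
    "<clustering_result> k* = %d (Davies-Bouldin %.4g) over k in {%s}\n",
    x$k_star, min(x$db_by_k$db), paste(x$db_by_k$k, collapse = ", ")
  ))
  invisible(x)
}

#' @method tidy clustering_result
#' @export
tidy.clustering_result <- function(x, ...) {
  tibble::tibble(
    sample_id = names(x$labels) %||% as.character(seq_along(x$labels)),
    cluster = unname(x$labels)
  )
}

#' @method glance clustering_result
#' @export
glance.clustering_result <- function(x, ...) {
  tibble::tibble(
    k_star = x$k_star,
    db_min = min(x$db_by_k$db),
    k_tested = nrow(x$db_by_k)
  )
}

#' Plot the Davies-Bouldin model-selection curve
#'
#' @param object A `clustering_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot clustering_result
#' @export
autoplot.clustering_result <- function(object, ...) {
  ggplot2::ggplot(object$db_by_k, ggplot2::aes(x = .data$k, y = .data$db)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$k_star, linetype = 2, colour = "#b2182b") +
    ggplot2::labs(x = "clusters k", y = "Davies-Bouldin index") +
    ggplot2::theme_minimal()
}

#' Cluster-diagnosis association test
#'
#' Collapses the clustering one-vs-rest onto the cluster most enriched for
#' the target diagnosis (highest within-cluster fraction of target samples;
#' ties toward the larger target count) and runs a two-sided Fisher exact
#' test on the resulting 2x2 cluster-by-diagnosis table.
#'
#' @param labels Cluster assignment per sample.
#' @param diagnosis Diagnosis label per sample (same length/order).
#' @param target The diagnosis whose grouping is tested (default
#'   `"case_FTDALS"`).
#' @return The two-sided p-value. Degenerate tables (a single cluster, or
#'   no target samples) return p = 1 with a warning.
#' @export
cluster_separation_test <- function(labels, diagnosis, target = "case_FTDALS") {
  stopifnot(length(labels) == length(diagnosis))
  is_target <- diagnosis %in% target
  if (length(unique(labels)) < 2 || !any(is_target) || all(is_target)) {
    warning("degenerate cluster/diagnosis table; p = 1", call. = FALSE)
    return(1)
  }
  frac <- tapply(is_target, labels, mean)
  cnt <- tapply(is_target, labels, sum)
  best <- names(frac)[order(-frac, -cnt)][1]
  in_best <- labels == best
  tab <- table(
    factor(in_best, levels = c(TRUE, FALSE)),
    factor(is_target, levels = c(TRUE, FALSE))
  )
  stats::fisher.test(tab)$p.value
}

#' Principal component analysis
#'
#' Centred (unscaled) PCA via the singular value decomposition.
#'
#' @param x Samples x features numeric matrix.
#' @param n_components Number of components to keep (at most
#'   `min(dim(x))`).
#' @return A `pca_result`: list with `scores` (samples x components),
#'   `explained_variance_ratio` (nonincreasing, sums to <= 1) and
#'   `loadings` (features x components, orthonormal columns).
#' @export
pca_components <- function(x, n_components = 2) {
  stopifnot(is.matrix(x), n_components >= 1, n_components <= min(dim(x)))
  fit <- stats::prcomp(x, center = TRUE, scale. = FALSE)
  keep <- seq_len(min(n_components, ncol(fit$rotation)))
  ratio <- fit$sdev^2 / sum(fit$sdev^2)
  structure(
    list(
      scores = fit$x[, keep, drop = FALSE],
      explained_variance_ratio = ratio[keep],
      loadings = fit$rotation[, keep, drop = FALSE]
    ),
    class = "pca_result"
  )
}

#' @export
print.pca_result <- function(x, ...) {
  cat(sprintf(
    "<pca_result> %d components; explained variance %s\n",
    ncol(x$scores),
    paste(sprintf("%.1f%%", 100 * x$explained_variance_ratio), collapse = ", ")
  ))
  invisible(x)
}

#' @method tidy pca_result
#' @export
tidy.pca_result <- function(x, ...) {
  out <- tibble::as_tibble(x$scores, rownames = "sample_id")
  out
}

#' Scatter plot of the first two principal components
#'
#' @param object A `pca_result`.
#' @param colour_by Optional vector (length = samples) used for colour.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot pca_result
#' @export
autoplot.pca_result <- function(object, colour_by = NULL, ...) {
  d <- tidy.pca_result(object)
  if (!is.null(colour_by)) d$colour_by <- colour_by
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$PC1, y = .data$PC2))
  p <- if (is.null(colour_by)) {
    p + ggplot2::geom_point()
  } else {
    p + ggplot2::geom_point(ggplot2::aes(colour = .data$colour_by)) +
      ggplot2::labs(colour = NULL)
  }
  p + ggplot2::labs(
    x = sprintf("PC1 (%.1f%%)", 100 * object$explained_variance_ratio[1]),
    y = sprintf("PC2 (%.1f%%)", 100 * object$explained_variance_ratio[2])
  ) +
    ggplot2::theme_minimal()
}
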