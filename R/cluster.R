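#' Two-cluster separation purity
#'
#' Quantifies the "perfect separation in two clusters" heatmap claim:
#' samples (columns) are clustered by agglomerative complete-linkage on
#' Euclidean distances, the tree is cut at two clusters, and purity is the
#' fraction of samples correctly grouped under the best matching of clusters
#' to the two true labels. Purity 1 means the two-cluster cut reproduces the
#' labels exactly; 0.5 is chance for balanced labels. Columns are ordered by
#' sample id before clustering so distance ties resolve deterministically.
#'
#' @param expr A feature-Z-scored expression matrix (see [zscore_rows()])
#'   restricted to the features of interest.
#' @param labels Binary label per sample: a vector aligned with `expr`'s
#'   columns, or named by sample id.
#' @return A `separation_result` list: `purity`, `clusters` (tibble
#'   sample_id, cluster, label), `linkage = "complete"`,
#'   `metric = "euclidean"`.
#' @export
two_cluster_purity <- function(expr, labels) {
  if (!is.matrix(expr) || !is.numeric(expr)) stopf("`expr` must be a numeric matrix")
  if (ncol(expr) < 4) stopf("need at least 4 samples to cut two clusters")
  if (!is.null(names(labels))) {
    labels <- labels[colnames(expr)]
  }
  if (length(labels) != ncol(expr) || anyNA(labels)) {
    stopf("`labels` must provide one non-missing label per sample")
  }
  labels <- as.character(labels)
  if (length(unique(labels)) != 2 || min(table(labels)) < 2) {
    stopf("`labels` must have exactly two levels with >= 2 samples each")
  }
  ord <- order(colnames(expr))
  expr <- expr[, ord, drop = FALSE]
  labels <- labels[ord]
  hc <- stats::hclust(stats::dist(t(expr), method = "euclidean"),
                      method = "complete")
  cl <- stats::cutree(hc, k = 2)
  tab <- table(cl, labels)
  # best matching of the two clusters onto the two labels
  correct <- max(tab[1, 1] + tab[2, 2], tab[1, 2] + tab[2, 1])
  structure(list(
    purity = correct / ncol(expr),
    clusters = tibble::tibble(sample_id = colnames(expr),
                              cluster = unname(cl), label = labels),
    linkage = "complete",
    metric = "euclidean"
  ), class = "separation_result")
}

#' @export
print.separation_result <- function(x, ...) {
  cat(sprintf("two-cluster separation purity: %.3f (%s linkage, %s distance)\n",
              x$purity, x$linkage, x$metric))
  invisible(x)
}

#' @export
tidy.separation_result <- function(x, ...) x$clusters

#' @export
glance.separation_result <- function(x, ...) {
  tibble::tibble(purity = x$purity, n = nrow(x$clusters),
                 linkage = x$linkage, metric = x$metric)
}
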