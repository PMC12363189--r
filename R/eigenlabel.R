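#' A/B feature classification from the leading eigenvector
#'
#' Eigendecomposes a within-dataset Spearman correlation matrix and labels
#' each feature by the sign of its entry in the leading eigenvector (largest
#' eigenvalue): positive entries are type A, negative entries type B. Because
#' an eigenvector is defined only up to sign, the convention here fixes the
#' sign so the entry sum is >= 0 (if the sum is exactly 0, so that the first
#' feature's entry is non-negative); exact-zero entries are labeled A. Labels
#' are therefore meaningful up to a global A/B swap.
#'
#' @param corr Symmetric correlation matrix with unit diagonal and feature
#'   dimnames.
#' @return A data frame with columns `feature`, `label` (`"A"`/`"B"`) and
#'   `eigenvector_entry`, plus attribute `"explained_variance"` (leading
#'   eigenvalue over the sum of eigenvalues).
#' @export
ab_classify <- function(corr) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    stop("`corr` must be a square matrix")
  if (anyNA(corr)) stop("`corr` must not contain missing entries")
  if (max(abs(corr - t(corr))) > 1e-8) stop("`corr` must be symmetric")
  eig <- eigen(corr, symmetric = TRUE)
  v <- eig$vectors[, 1]
  s <- sum(v)
  if (s < 0 || (s == 0 && v[1] < 0)) v <- -v
  feats <- colnames(corr)
  if (is.null(feats)) feats <- paste0("F", seq_len(ncol(corr)))
  out <- data.frame(feature = feats,
                    label = ifelse(v >= 0, "A", "B"),
                    eigenvector_entry = v,
                    stringsAsFactors = FALSE)
  attr(out, "explained_variance") <- eig$values[1] / sum(eig$values)
  out
}

#' Hierarchical clustering of a correlation matrix
#'
#' Agglomerative clustering of the features using the correlation distance
#' between the rows of the correlation matrix (`1 - cor(row_i, row_j)`, the
#' "correlation" metric of common clustermap tools) with average linkage.
#' Deterministic for a fixed input order.
#'
#' @param corr Symmetric correlation matrix with feature dimnames.
#' @return A `cluster_order` object: list with `hclust` (the tree), `order`
#'   (leaf indices) and `labels` (leaf names in display order).
#' @export
cluster_order <- function(corr) {
  if (!is.matrix(corr) || nrow(corr) != ncol(corr))
    stop("`corr` must be a square matrix")
  if (nrow(corr) < 2) stop("need at least 2 features")
  rc <- suppressWarnings(stats::cor(t(corr)))
  rc[is.na(rc)] <- 0        # constant rows: maximal distance to everything
  d <- stats::as.dist(1 - rc)
  hc <- stats::hclust(d, method = "average")
  structure(list(hclust = hc, order = hc$order,
                 labels = hc$labels[hc$order]),
            class = "cluster_order")
}

#' Export a dendrogram in Newick format
#'
#' @param co A `cluster_order` from [cluster_order()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_dendrogram_newick <- function(co, path) {
  stopifnot(inherits(co, "cluster_order"))
  phy <- ape::as.phylo(co$hclust)
  ape::write.tree(phy, file = path)
  invisible(path)
}
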