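#' Residualize features on subject
#'
#' Fits, per feature, the saturated one-factor linear model `value ~ subject`
#' and returns its residuals (for an ordinary linear model with unit working
#' weights the Pearson residuals equal the raw residuals, so this is exact
#' subject-mean centering). Removes inter-subject variance so the remaining
#' variation is temporal.
#'
#' @param ft Transformed [feature_table()] (log2 metabolites / arcsine-sqrt
#'   microbiome).
#' @param metadata Data frame with `Sample` and the subject column.
#' @param subject_col Metadata column holding subject labels.
#' @return A `residual_table`: list with `values` (samples x features residual
#'   matrix), `subject` (per-sample labels) and `source` (dataset type).
#'   Subjects observed only once get residual 0 (with a warning).
#' @export
residualize <- function(ft, metadata, subject_col = "Subject") {
  stopifnot(inherits(ft, "feature_table"))
  metadata <- metadata[match(sample_ids(ft), metadata$Sample), , drop = FALSE]
  subj <- metadata[[subject_col]]
  if (anyNA(subj)) stop("every sample needs a subject label")
  if (any(table(subj) == 1L))
    warning("subject(s) with a single sample: their residuals are 0")
  v <- ft$values
  res <- apply(v, 2L, function(x) x - stats::ave(x, subj))
  dimnames(res) <- dimnames(v)
  structure(list(values = res, subject = as.character(subj), source = ft$type),
            class = "residual_table")
}

#' All-pairs Spearman correlation with t-approximation p-values
#'
#' Spearman rho computed as the Pearson correlation of mid-ranks (average rank
#' for ties); two-sided p-values from the `t = rho * sqrt((n-2)/(1-rho^2))`
#' approximation on `n - 2` degrees of freedom. Constant features yield `NA`
#' rho/p and are excluded downstream from FDR.
#'
#' @param X A `residual_table` (or `feature_table`).
#' @param Y Optional second table sharing `X`'s samples in the same order;
#'   omit for within-dataset correlation.
#' @return List with matrices `rho` and `p` (features of X x features of Y)
#'   and the sample size `n`.
#' @export
spearman_all_pairs <- function(X, Y = NULL) {
  xv <- X$values
  yv <- if (is.null(Y)) xv else Y$values
  if (nrow(xv) != nrow(yv) ||
      (!is.null(rownames(xv)) && !is.null(rownames(yv)) &&
       !identical(rownames(xv), rownames(yv))))
    stop("X and Y must share the same samples in the same order")
  n <- nrow(xv)
  if (n < 4) stop("need at least 4 samples")
  rx <- apply(xv, 2L, rank)
  ry <- if (is.null(Y)) rx else apply(yv, 2L, rank)
  const_x <- apply(xv, 2L, function(z) length(unique(z)) == 1L)
  const_y <- apply(yv, 2L, function(z) length(unique(z)) == 1L)
  rho <- suppressWarnings(stats::cor(rx, ry))
  rho[const_x, ] <- NA_real_
  rho[, const_y] <- NA_real_
  r2 <- pmin(rho^2, 1 - 1e-15)
  tstat <- rho * sqrt((n - 2) / (1 - r2))
  p <- 2 * stats::pt(abs(tstat), df = n - 2, lower.tail = FALSE)
  p[abs(rho) >= 1 - 1e-12] <- 0
  dimnames(rho) <- dimnames(p) <- list(colnames(xv), colnames(yv))
  list(rho = rho, p = p, n = n)
}

#' Assemble association records from correlation matrices
#'
#' Flattens rho/p matrices into one row per tested pair. Within-dataset pairs
#' are stored once, in canonical (upper-triangle) order; constant-feature
#' pairs (`NA` rho) are dropped with their count recorded in the
#' `"n_excluded"` attribute.
#'
#' @param sp Output of [spearman_all_pairs()].
#' @param pair_type One of `"met-met"`, `"bact-bact"`, `"bact-met"`.
#' @param within Logical: was the correlation within one dataset? (keeps the
#'   upper triangle only).
#' @return Data frame with `feature_x`, `feature_y`, `pair_type`, `rho`, `p`.
#' @export
association_records <- function(sp, pair_type = c("met-met", "bact-bact", "bact-met"),
                                within = pair_type != "bact-met") {
  pair_type <- match.arg(pair_type)
  rho <- sp$rho; p <- sp$p
  if (within) {
    keep <- upper.tri(rho)
  } else {
    keep <- matrix(TRUE, nrow(rho), ncol(rho))
  }
  idx <- which(keep, arr.ind = TRUE)
  out <- data.frame(feature_x = rownames(rho)[idx[, 1]],
                    feature_y = colnames(rho)[idx[, 2]],
                    pair_type = pair_type,
                    rho = rho[keep], p = p[keep],
                    stringsAsFactors = FALSE)
  n_all <- nrow(out)
  out <- out[!is.na(out$rho), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "n_excluded") <- n_all - nrow(out)
  out
}

#' Benjamini-Hochberg adjustment per association family
#'
#' Applies BH separately within each `pair_type` family (met-met, bact-bact,
#' bact-met), mirroring per-dataset-pair testing; q is monotone nondecreasing
#' in p within a family and `q >= p` always.
#'
#' @param records Data frame from [association_records()] (families may be
#'   concatenated with `rbind`).
#' @param alpha Significance threshold recorded in the `significant` column
#'   (default 0.05).
#' @return `records` with added `q` and `significant` columns.
#' @export
adjust_fdr <- function(records, alpha = 0.05) {
  if (nrow(records) == 0L) {
    records$q <- numeric(0)
    records$significant <- logical(0)
    return(records)
  }
  records$q <- stats::ave(records$p, records$pair_type,
                          FUN = function(p) stats::p.adjust(p, method = "BH"))
  records$significant <- records$q < alpha
  records
}

# internal: nested-block descent used by rank_blocks
descend_blocks <- function(sig, minq, xs, ys, xtree, ytree, density) {
  nsig <- sum(sig[xs, ys])
  if (nsig == 0L) return(NULL)
  dens <- nsig / (length(xs) * length(ys))
  # report when the density is exceeded (strict), or saturated at 1 (so a
  # fully significant 1x1 block is always reportable whatever the parameter)
  if (dens > density || dens == 1)
    return(list(list(x_features = rownames(sig)[xs], y_features = colnames(sig)[ys],
                     score = min(minq[xs, ys][sig[xs, ys]]))))
  split_node <- function(tree, leaves) {
    # children of the subtree spanning `leaves` (leaf index sets)
    if (length(leaves) == 1L) return(list(leaves))
    sub <- cut_to_groups(tree, leaves)
    sub
  }
  if (length(xs) >= length(ys) && length(xs) > 1L) {
    parts <- split_node(xtree, xs)
    out <- lapply(parts, function(px)
      descend_blocks(sig, minq, px, ys, xtree, ytree, density))
  } else if (length(ys) > 1L) {
    parts <- split_node(ytree, ys)
    out <- lapply(parts, function(py)
      descend_blocks(sig, minq, xs, py, xtree, ytree, density))
  } else {
    return(NULL)  # 1x1 block below density cannot happen (density of 1x1 is 1)
  }
  do.call(c, out)
}

# internal: split a set of leaves into the two child clades of its spanning
# subtree (fallback: split the leaf order in half when the set is not a clade)
cut_to_groups <- function(tree, leaves) {
  hc <- tree$hclust
  n <- length(hc$order)
  # raise k until the leaf set is split across groups; cutree heights are
  # monotone so this finds the first clade boundary inside the set
  for (k in 2:n) {
    grp <- stats::cutree(hc, k = k)
    g <- grp[leaves]
    if (length(unique(g)) > 1L)
      return(split(leaves, g))
  }
  split(leaves, cumsum(seq_along(leaves) <= length(leaves) / 2))
}

#' Rank significant association blocks under coupled dendrograms
#'
#' A deterministic surrogate for hierarchical block testing: starting from the
#' root pair of the two feature dendrograms, a (sub-block of the) q-matrix is
#' reported when its fraction of significant cells reaches `density`,
#' otherwise the larger-side clade is split and the descent recurses. Reported
#' blocks are disjoint, each contains at least one significant pair, and they
#' are scored by their minimum q (rank 1 = smallest).
#'
#' @param rho,q Matrices over X-features (rows) x Y-features (columns).
#' @param q_threshold Significance threshold on q (default 0.05).
#' @param x_order,y_order `cluster_order` objects (from [cluster_order()]) for
#'   the row and column feature sets.
#' @param density Minimum fraction of significant cells for a reported block
#'   (default 0.5).
#' @return Data frame with `rank`, `score`, `x_features`, `y_features`
#'   (semicolon-delimited), or an empty data frame when nothing is significant.
#' @export
rank_blocks <- function(rho, q, q_threshold = 0.05, x_order, y_order,
                        density = 0.5) {
  stopifnot(identical(dim(rho), dim(q)))
  sig <- !is.na(q) & q < q_threshold
  empty <- data.frame(rank = integer(0), score = numeric(0),
                      x_features = character(0), y_features = character(0),
                      stringsAsFactors = FALSE)
  if (!any(sig)) return(empty)
  qq <- q
  qq[is.na(qq)] <- 1
  blocks <- descend_blocks(sig, qq, seq_len(nrow(q)), seq_len(ncol(q)),
                           x_order, y_order, density)
  if (is.null(blocks) || !length(blocks)) return(empty)
  score <- vapply(blocks, `[[`, 0, "score")
  o <- order(score)
  data.frame(rank = seq_along(o), score = score[o],
             x_features = vapply(blocks[o], function(b)
               paste(b$x_features, collapse = ";"), ""),
             y_features = vapply(blocks[o], function(b)
               paste(b$y_features, collapse = ";"), ""),
             stringsAsFactors = FALSE)
}
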