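#' Bray-Curtis dissimilarity between samples
#'
#' `d(i, j) = sum|x_i - x_j| / sum(x_i + x_j)`, computed with
#' [vegan::vegdist()]. Bounded in \[0, 1\] for non-negative data.
#'
#' @param ft [feature_table()] with non-negative values and no all-zero rows.
#' @return A `distance_matrix`: symmetric numeric matrix with zero diagonal and
#'   sample ids as dimnames.
#' @export
bray_curtis <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  if (anyNA(ft$values)) stop("missing values present; impute first")
  if (any(ft$values < 0)) stop("values must be non-negative")
  if (any(rowSums(ft$values) == 0)) stop("all-zero sample row")
  d <- as.matrix(vegan::vegdist(ft$values, method = "bray"))
  dimnames(d) <- list(sample_ids(ft), sample_ids(ft))
  structure(d, class = c("distance_matrix", "matrix", "array"))
}

# internal: validate a distance matrix
check_dist <- function(d) {
  if (!is.matrix(d) || nrow(d) != ncol(d)) stop("`d` must be a square matrix")
  if (max(abs(d - t(d))) > 1e-12) stop("`d` must be symmetric")
  if (any(abs(diag(d)) > 1e-12)) stop("`d` must have a zero diagonal")
  invisible(d)
}

#' Principal coordinates analysis
#'
#' Classical metric scaling (Torgerson) of the double-centered `-d^2/2` matrix
#' via [stats::cmdscale()]. Axes with non-positive eigenvalues are dropped
#' (no negative-eigenvalue correction is applied); the variance explained by
#' each retained axis is its eigenvalue divided by the sum of positive
#' eigenvalues.
#'
#' @param d A `distance_matrix` (or symmetric matrix) over at least 3 samples.
#' @return A list with `coordinates` (samples x axes), `variance_explained`
#'   (descending, sums to 1 over retained axes) and `eigenvalues`.
#' @export
pcoa <- function(d) {
  d <- unclass(d)
  check_dist(d)
  if (nrow(d) < 3) stop("PCoA requires at least 3 samples")
  k <- nrow(d) - 1
  # k = n-1 is requested and surplus axes dropped below; cmdscale warns when
  # fewer than k eigenvalues are positive, which is expected here
  fit <- suppressWarnings(stats::cmdscale(stats::as.dist(d), k = k, eig = TRUE))
  pos <- fit$eig > sqrt(.Machine$double.eps) * max(abs(fit$eig))
  npos <- sum(pos)
  coords <- fit$points[, seq_len(min(npos, ncol(fit$points))), drop = FALSE]
  colnames(coords) <- paste0("PCo", seq_len(ncol(coords)))
  list(coordinates = coords,
       variance_explained = fit$eig[seq_len(ncol(coords))] / sum(fit$eig[pos]),
       eigenvalues = fit$eig)
}

#' Marginal PERMANOVA with restricted permutations
#'
#' Partitions the variance of a dissimilarity matrix over metadata terms with
#' [vegan::adonis2()] using marginal (each term conditional on all others)
#' sums of squares. Permutations are restricted to shuffle sample labels only
#' within levels of `strata` (one metadata column or several, combined into
#' their interaction cells). P-values use the add-one convention
#' `(1 + #permuted F >= observed) / (1 + n_perm)`.
#'
#' @param d `distance_matrix` over the samples of `metadata`.
#' @param metadata Data frame, one row per sample, in the order of `d` (or with
#'   a `Sample` column matching `rownames(d)`).
#' @param terms Character vector of metadata columns to test.
#' @param strata Optional character vector of metadata columns defining the
#'   permutation blocks.
#' @param n_perm Number of permutations (default 9999).
#' @param seed Integer seed for the permutation stream.
#' @param by Passed to [vegan::adonis2()]; `"margin"` (default) tests each
#'   term conditional on the others.
#' @return Data frame with columns `term`, `df`, `SumOfSqs`, `pseudo_F`, `R2`,
#'   `p`, `n_perm` (residual and total rows included with `NA` statistics).
#' @export
permanova <- function(d, metadata, terms, strata = NULL, n_perm = 9999,
                      seed = 1L, by = "margin") {
  d <- unclass(d)
  check_dist(d)
  if ("Sample" %in% names(metadata) && !is.null(rownames(d)))
    metadata <- metadata[match(rownames(d), metadata$Sample), , drop = FALSE]
  if (nrow(metadata) != nrow(d))
    stop("`metadata` must have one row per sample of `d`")
  missing_terms <- setdiff(c(terms, strata), names(metadata))
  if (length(missing_terms))
    stop("metadata columns not found: ", paste(missing_terms, collapse = ", "))
  for (tm in terms) {
    v <- metadata[[tm]]
    if (!is.numeric(v) && length(unique(v)) < 2)
      stop(sprintf("term `%s` has a single level (degenerate design)", tm))
  }
  ctrl <- if (is.null(strata)) {
    permute::how(nperm = n_perm)
  } else {
    blocks <- interaction(metadata[strata], drop = TRUE)
    tab <- table(blocks)
    if (any(tab < 2))
      warning("strata with a single sample: term unpermutable within them")
    permute::how(nperm = n_perm, blocks = blocks)
  }
  fml <- stats::as.formula(paste("stats::as.dist(d) ~", paste(terms, collapse = " + ")))
  set.seed(seed)
  fit <- vegan::adonis2(fml, data = metadata, permutations = ctrl, by = by)
  data.frame(term = rownames(fit), df = fit$Df, SumOfSqs = fit$SumOfSqs,
             pseudo_F = fit$F, R2 = fit$R2, p = fit$`Pr(>F)`,
             n_perm = n_perm, row.names = NULL, stringsAsFactors = FALSE)
}

#' Differential metabolite analysis with a mixed-effects model
#'
#' Fits, per metabolite, `value ~ Treatment_Condition + (1 | Subject)` on
#' median-scaled, log2(x+1)-transformed abundances with [lmerTest::lmer()]
#' (Satterthwaite coefficient tests), extracts each condition's contrast
#' against the `Control` reference as a log2 fold change, and applies
#' Benjamini-Hochberg correction over the pooled (metabolite x condition)
#' p-vector.
#'
#' @param ft Metabolite [feature_table()] on the log2 scale.
#' @param metadata Data frame with `Sample`, the subject column and the
#'   condition column.
#' @param condition_col,subject_col Metadata column names (defaults
#'   `"Treatment_Condition"`, `"Subject"`).
#' @param reference Reference condition level (default `"Control"`).
#' @return Data frame with columns `metabolite`, `condition`, `log2FC`, `p`,
#'   `q`, `significant` (q < 0.05), sorted by `q`.
#' @export
lmm_differential <- function(ft, metadata, condition_col = "Treatment_Condition",
                             subject_col = "Subject", reference = "Control") {
  stopifnot(inherits(ft, "feature_table"))
  metadata <- metadata[match(sample_ids(ft), metadata$Sample), , drop = FALSE]
  cond <- metadata[[condition_col]]
  if (!reference %in% cond)
    stop(sprintf("reference condition `%s` absent from the data", reference))
  if (is.factor(cond) && any(table(cond) == 0)) {
    warning("dropping condition levels with zero samples: ",
            paste(levels(cond)[table(cond) == 0], collapse = ", "))
    cond <- droplevels(cond)
  }
  cond <- stats::relevel(factor(cond), ref = reference)
  subj <- factor(metadata[[subject_col]])
  res <- lapply(feature_ids(ft), function(m) {
    df <- data.frame(value = ft$values[, m], cond = cond, subj = subj)
    fit <- suppressMessages(suppressWarnings(
      lmerTest::lmer(value ~ cond + (1 | subj), data = df,
                     control = lme4::lmerControl(check.conv.singular = "ignore"))))
    cf <- stats::coef(summary(fit))
    rows <- grep("^cond", rownames(cf), value = TRUE)
    data.frame(metabolite = m, condition = sub("^cond", "", rows),
               log2FC = cf[rows, "Estimate"], p = cf[rows, "Pr(>|t|)"],
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$q <- stats::p.adjust(out$p, method = "BH")
  out$significant <- out$q < 0.05
  out[order(out$q, out$p), , drop = FALSE]
}
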