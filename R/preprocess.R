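#' Remove metabolites with excessive missingness
#'
#' Drops every metabolite whose fraction of missing cells is strictly greater
#' than `max_missing_fraction`. The boundary is strict: a feature missing in
#' exactly 70% of samples is kept under the default. Zeros count as observed
#' values; only `NA` cells are missing.
#'
#' @param ft Metabolite [feature_table()].
#' @param max_missing_fraction Maximum tolerated missing fraction (default 0.70).
#' @return Filtered `feature_table`; feature order preserved. The removal report
#'   is attached as attribute `"report"` (character vector of log lines).
#' @export
filter_metabolites <- function(ft, max_missing_fraction = 0.70) {
  stopifnot(inherits(ft, "feature_table"))
  if (ft$type != "metabolome") stop("`ft` must be a metabolite table")
  if (nrow(ft$values) == 0L) stop("metabolite table has zero samples")
  if (max_missing_fraction <= 0 || max_missing_fraction >= 1)
    stop("`max_missing_fraction` must be in (0, 1)")
  miss_frac <- colMeans(is.na(ft$values))
  keep <- miss_frac <= max_missing_fraction
  out <- ft_subset(ft, features = which(keep))
  attr(out, "report") <- c(
    sprintf("filter_metabolites: removed %d/%d features with missing fraction > %.2f",
            sum(!keep), length(keep), max_missing_fraction),
    if (any(!keep)) sprintf("  removed: %s (%.0f%% missing)",
                            colnames(ft$values)[!keep], 100 * miss_frac[!keep]))
  out
}

#' Median-impute and median-scale metabolites
#'
#' Missing cells of each metabolite are imputed with the feature-wise median of
#' its observed values; every feature is then divided by that same median (the
#' median excluding imputed cells), so that after scaling the median of each
#' feature's non-imputed cells is exactly 1. Imputed cells are flagged in the
#' returned table's `imputed` matrix.
#'
#' @param ft Post-filter metabolite [feature_table()]; every feature must have
#'   at least one observed value.
#' @return `feature_table` with no missing values and populated `imputed` flags.
#' @export
impute_and_median_scale <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  if (ft$type != "metabolome") stop("`ft` must be a metabolite table")
  v <- ft$values
  if (any(colSums(!is.na(v)) == 0L))
    stop("all-missing feature encountered; run filter_metabolites first")
  med <- apply(v, 2L, stats::median, na.rm = TRUE)
  if (any(med == 0))
    stop("feature with zero median cannot be median-scaled")
  imputed <- is.na(v)
  v <- sweep(v, 2L, med, function(x, m) ifelse(is.na(x), m, x))
  v <- sweep(v, 2L, med, "/")
  ft_replace(ft, v, imputed = imputed)
}

#' Normalize metabolites by panel
#'
#' Within each sample, divides every metabolite by the mean abundance of all
#' metabolites belonging to the same panel, so each sample's per-panel mean is
#' 1. Used before ordination-based analyses.
#'
#' @param ft Metabolite [feature_table()]; `feature_meta` must carry a complete
#'   `panel` column.
#' @return Panel-normalized `feature_table`.
#' @export
panel_normalize <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  if (!"panel" %in% names(ft$feature_meta) || anyNA(ft$feature_meta$panel))
    stop("every feature must carry a panel annotation")
  if (anyNA(ft$values))
    stop("impute missing values before panel normalization")
  v <- ft$values
  for (p in unique(ft$feature_meta$panel)) {
    idx <- which(ft$feature_meta$panel == p)
    pm <- rowMeans(v[, idx, drop = FALSE])
    v[, idx] <- v[, idx, drop = FALSE] / pm
  }
  ft_replace(ft, v)
}

#' Log2 transform with pseudocount
#'
#' `x -> log2(x + pseudocount)`, the variance-stabilizing transform applied to
#' median-scaled metabolites ahead of differential and correlation analysis.
#'
#' @param ft [feature_table()] with non-negative values.
#' @param pseudocount Added before taking logs (default 1).
#' @return Transformed `feature_table`.
#' @export
log2_pseudo <- function(ft, pseudocount = 1) {
  stopifnot(inherits(ft, "feature_table"))
  if (anyNA(ft$values)) stop("missing values present; impute first")
  if (any(ft$values < 0)) stop("negative values cannot be log-transformed")
  ft_replace(ft, log2(ft$values + pseudocount))
}

#' Filter a microbiome count table
#'
#' Removes features present (count > 0) in fewer than `min_sample_presence`
#' samples, then removes samples whose total reads fall strictly below
#' `min_total_reads`. Boundaries are strict: a sample with exactly 1,000 reads
#' is kept under the default.
#'
#' @param ft Microbiome count [feature_table()].
#' @param min_sample_presence Minimum number of samples a feature must appear
#'   in (default 2, i.e. singleton features are dropped).
#' @param min_total_reads Read-depth floor for samples (default 1000).
#' @return Filtered `feature_table` with a `"report"` attribute listing
#'   removals (also warns when the result is empty).
#' @export
filter_microbiome <- function(ft, min_sample_presence = 2, min_total_reads = 1000) {
  stopifnot(inherits(ft, "feature_table"))
  if (ft$type != "microbiome") stop("`ft` must be a microbiome table")
  presence <- colSums(ft$values > 0)
  keep_f <- presence >= min_sample_presence
  depth <- rowSums(ft$values)
  keep_s <- depth >= min_total_reads
  out <- ft_subset(ft, samples = which(keep_s), features = which(keep_f))
  if (nrow(out$values) == 0L || ncol(out$values) == 0L)
    warning("filter_microbiome produced an empty table")
  attr(out, "report") <- c(
    sprintf("filter_microbiome: removed %d/%d features present in < %d samples",
            sum(!keep_f), length(keep_f), min_sample_presence),
    sprintf("filter_microbiome: removed %d/%d samples with total reads < %d",
            sum(!keep_s), length(keep_s), min_total_reads),
    if (any(!keep_s)) sprintf("  removed sample: %s (%d reads)",
                              rownames(ft$values)[!keep_s], depth[!keep_s]))
  out
}

#' Convert counts to relative abundance
#'
#' @param ft Microbiome count [feature_table()]; every sample total must be
#'   positive.
#' @return `feature_table` whose rows sum to 1.
#' @export
relative_abundance <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  tot <- rowSums(ft$values)
  if (any(tot <= 0)) stop("sample with zero total count")
  ft_replace(ft, ft$values / tot)
}

#' Arcsine square-root transform
#'
#' `x -> asin(sqrt(x))`, the variance-stabilizing transform for relative
#' abundances ahead of correlation analysis.
#'
#' @param ft [feature_table()] with values in \[0, 1\].
#' @return Transformed `feature_table`.
#' @export
arcsine_sqrt <- function(ft) {
  stopifnot(inherits(ft, "feature_table"))
  if (anyNA(ft$values) || any(ft$values < 0) || any(ft$values > 1))
    stop("values must lie in [0, 1]")
  ft_replace(ft, asin(sqrt(ft$values)))
}
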