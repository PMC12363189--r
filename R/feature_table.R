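#' Construct a feature table
#'
#' The central data container of the pipeline: a samples x features numeric
#' matrix plus per-feature annotation (metabolite panel or genus name), the
#' dataset type, and an optional per-cell imputation-marker matrix (metabolite
#' tables only).
#'
#' @param values Numeric matrix, samples as rows, features as columns. Row and
#'   column names are required and must be unique.
#' @param feature_meta Data frame with one row per feature. Must contain a
#'   `feature` column matching `colnames(values)`; metabolite tables carry a
#'   `panel` column (one of `"SCFA"`, `"BA"`, `"AA"`), microbiome tables a
#'   `genus` column.
#' @param type Either `"microbiome"` (non-negative counts) or `"metabolome"`
#'   (positive abundances, `NA` allowed for missing cells).
#' @param imputed Optional logical matrix, same shape as `values`, marking
#'   imputed cells. Only allowed for metabolite tables.
#'
#' @return An object of class `feature_table`: a list with elements `values`,
#'   `feature_meta`, `type`, `imputed`.
#' @export
feature_table <- function(values, feature_meta, type = c("microbiome", "metabolome"),
                          imputed = NULL) {
  type <- match.arg(type)
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have sample row names and feature column names")
  if (anyDuplicated(rownames(values)))
    stop("duplicate sample identifiers")
  if (anyDuplicated(colnames(values)))
    stop("duplicate feature identifiers")
  if (!is.data.frame(feature_meta) || !"feature" %in% names(feature_meta))
    stop("`feature_meta` must be a data frame with a `feature` column")
  if (!setequal(feature_meta$feature, colnames(values)))
    stop("`feature_meta$feature` must match the columns of `values`")
  feature_meta <- feature_meta[match(colnames(values), feature_meta$feature), ,
                               drop = FALSE]
  rownames(feature_meta) <- NULL
  if (type == "microbiome") {
    if (anyNA(values)) stop("microbiome counts must not contain missing values")
    if (any(values < 0)) stop("microbiome counts must be non-negative")
    if (!is.null(imputed)) stop("imputation markers only apply to metabolite tables")
  }
  if (!is.null(imputed)) {
    if (!is.logical(imputed) || !identical(dim(imputed), dim(values)))
      stop("`imputed` must be a logical matrix of the same shape as `values`")
    dimnames(imputed) <- dimnames(values)
  }
  structure(list(values = values, feature_meta = feature_meta, type = type,
                 imputed = imputed),
            class = "feature_table")
}

#' @export
print.feature_table <- function(x, ...) {
  cat(sprintf("<feature_table> %s: %d samples x %d features\n",
              x$type, nrow(x$values), ncol(x$values)))
  if (anyNA(x$values))
    cat(sprintf("  missing cells: %d\n", sum(is.na(x$values))))
  if (!is.null(x$imputed))
    cat(sprintf("  imputed cells: %d\n", sum(x$imputed)))
  invisible(x)
}

#' @export
dim.feature_table <- function(x) dim(x$values)

# internal: replace values (and keep dimnames) while preserving metadata
ft_replace <- function(ft, values, imputed = ft$imputed) {
  ft$values <- values
  ft$imputed <- imputed
  ft
}

# internal: subset a feature table by sample / feature index or name
ft_subset <- function(ft, samples = NULL, features = NULL) {
  v <- ft$values
  if (!is.null(samples)) v <- v[samples, , drop = FALSE]
  if (!is.null(features)) v <- v[, features, drop = FALSE]
  fm <- ft$feature_meta[match(colnames(v), ft$feature_meta$feature), , drop = FALSE]
  rownames(fm) <- NULL
  imp <- ft$imputed
  if (!is.null(imp)) imp <- imp[rownames(v), colnames(v), drop = FALSE]
  structure(list(values = v, feature_meta = fm, type = ft$type, imputed = imp),
            class = "feature_table")
}

#' Sample identifiers of a feature table
#' @param ft A [feature_table()].
#' @return Character vector of sample ids in table order.
#' @export
sample_ids <- function(ft) rownames(ft$values)

#' Feature identifiers of a feature table
#' @param ft A [feature_table()].
#' @return Character vector of feature ids in table order.
#' @export
feature_ids <- function(ft) colnames(ft$values)
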