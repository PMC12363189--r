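# Readers and writers for the pipeline's plain-text artifacts. All tables are
# TSV; feature tables store samples as rows with the sample id in the first
# column, and feature annotations travel in a companion TSV.

#' Write a feature table (and its annotation) as TSV
#'
#' @param ft A [feature_table()].
#' @param path Values TSV path (first column `Sample`, then one column per
#'   feature).
#' @param meta_path Optional annotation TSV path (defaults to
#'   `<path>.features.tsv`).
#' @return `path`, invisibly.
#' @export
write_feature_table <- function(ft, path, meta_path = paste0(path, ".features.tsv")) {
  stopifnot(inherits(ft, "feature_table"))
  df <- data.frame(Sample = sample_ids(ft), ft$values, check.names = FALSE,
                   stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(ft$feature_meta, meta_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' Read a feature table written by [write_feature_table()]
#'
#' @param path Values TSV path.
#' @param type `"microbiome"` or `"metabolome"`.
#' @param meta_path Annotation TSV path (defaults to `<path>.features.tsv`).
#' @return A [feature_table()].
#' @export
read_feature_table <- function(path, type = c("microbiome", "metabolome"),
                               meta_path = paste0(path, ".features.tsv")) {
  type <- match.arg(type)
  df <- utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                          stringsAsFactors = FALSE)
  v <- as.matrix(df[, -1, drop = FALSE])
  rownames(v) <- df[[1]]
  fm <- utils::read.table(meta_path, sep = "\t", header = TRUE,
                          check.names = FALSE, stringsAsFactors = FALSE)
  feature_table(v, fm, type = type)
}

#' Write sample metadata as TSV
#' @param metadata Metadata data frame.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_metadata <- function(metadata, path) {
  utils::write.table(metadata, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read sample metadata written by [write_metadata()]
#' @param path Metadata TSV path.
#' @return Data frame.
#' @export
read_metadata <- function(path) {
  utils::read.table(path, sep = "\t", header = TRUE, check.names = FALSE,
                    stringsAsFactors = FALSE)
}

#' Write association records as TSV
#'
#' Columns: `feature_x`, `feature_y`, `pair_type`, `rho`, `p`, `q`,
#' `significant` (0/1).
#'
#' @param records Data frame from [adjust_fdr()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_associations <- function(records, path) {
  out <- records
  out$significant <- as.integer(out$significant)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read association records written by [write_associations()]
#' @param path Associations TSV path.
#' @return Data frame with a logical `significant` column.
#' @export
read_associations <- function(path) {
  out <- utils::read.table(path, sep = "\t", header = TRUE,
                           stringsAsFactors = FALSE)
  out$significant <- as.logical(out$significant)
  out
}

#' Export an association graph as GraphML
#'
#' @param g Graph from [build_graph()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_graphml <- function(g, path) {
  igraph::write_graph(g, path, format = "graphml")
  invisible(path)
}

#' Write a power-law fit (plus comparisons) as JSON
#'
#' @param fit A `power_law_fit` (optionally with bootstrap fields).
#' @param comparisons Optional data frame from [compare_distributions()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_power_law_json <- function(fit, comparisons = NULL, path) {
  obj <- list(xmin = fit$xmin, alpha = fit$alpha, ks_stat = fit$ks_stat,
              n_tail = fit$n_tail, n = fit$n,
              boot_p = fit$boot_p, n_boot = fit$n_boot)
  if (!is.null(comparisons)) obj$comparisons <- comparisons
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Write MCODE clusters as TSV
#'
#' Columns: `cluster_id`, `seed`, `score`, `members` (semicolon-delimited).
#'
#' @param clusters [mcode()] output.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_mcode_clusters <- function(clusters, path) {
  df <- if (length(clusters)) data.frame(
    cluster_id = seq_along(clusters),
    seed = vapply(clusters, `[[`, "", "seed"),
    score = vapply(clusters, `[[`, 0, "score"),
    members = vapply(clusters, function(cl) paste(cl$members, collapse = ";"), ""),
    stringsAsFactors = FALSE)
  else data.frame(cluster_id = integer(0), seed = character(0),
                  score = numeric(0), members = character(0))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a KCS table as TSV in the canonical column order
#'
#' Columns: Genus, KCS, MCODE status, Diff. Metab, degree (Bact-Bact), degree
#' (Bact-Metab), HiLo betweenness (Bact-Bact), HiLo betweenness (Bact-Metab).
#'
#' @param kcs Data frame from [kcs_table()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_kcs_table <- function(kcs, path) {
  out <- data.frame(Genus = kcs$genus, KCS = kcs$kcs,
                    `MCODE status` = kcs$mcode_status,
                    `Diff. Metab` = kcs$diff_metab,
                    `degree (Bact-Bact)` = kcs$degree_bb,
                    `degree (Bact-Metab)` = kcs$degree_bm,
                    `HiLo betweenness (Bact-Bact)` = kcs$hilo_bb,
                    `HiLo betweenness (Bact-Metab)` = kcs$hilo_bm,
                    check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write a simulation configuration as a YAML file
#' @param config A [sim_config()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sim_config <- function(config, path) {
  x <- unclass(config)
  x$panel_sizes <- as.list(x$panel_sizes)   # YAML drops names of atomic vectors
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a simulation configuration written by [write_sim_config()]
#' @param path YAML path.
#' @return A [sim_config()].
#' @export
read_sim_config <- function(path) {
  x <- yaml::read_yaml(path)
  x$panel_sizes <- unlist(x$panel_sizes)
  do.call(sim_config, x)
}

#' Write a distance matrix as square TSV with a header
#' @param d A `distance_matrix`.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_distance_matrix <- function(d, path) {
  df <- data.frame(Sample = rownames(d), unclass(d), check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write PCoA coordinates (with variance explained) as TSV
#' @param ord Output of [pcoa()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_pcoa_coordinates <- function(ord, path) {
  df <- data.frame(Sample = rownames(ord$coordinates), ord$coordinates,
                   check.names = FALSE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(sprintf("# variance_explained: %s",
                     paste(signif(ord$variance_explained, 6), collapse = "\t")),
             con)
  utils::write.table(df, con, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Write A/B feature labels as TSV
#' @param labels Output of [ab_classify()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_ab_labels <- function(labels, path) {
  utils::write.table(labels, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
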