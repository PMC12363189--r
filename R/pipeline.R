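#' Run the full association-network / keystone-scoring pipeline
#'
#' Chains every stage on an in-memory study (as produced by
#' [simulate_study()] or assembled from the readers in this package):
#'
#' 1. Metabolites: missingness filter, median imputation + scaling, log2(x+1).
#' 2. Microbiome: singleton-feature and read-depth filters, relative
#'    abundance, arcsine-sqrt; low-depth samples (and their metabolome
#'    partners) are excluded from the correlation stage onward.
#' 3. Differential metabolites via the subject-random-intercept mixed model
#'    (all samples).
#' 4. Subject residualization, all-against-all Spearman testing, BH per
#'    family (met-met / bact-bact / bact-met).
#' 5. Typed association graph, per-subgraph centralities, MCODE on the
#'    bacteria-bacteria and bacteria-metabolite subgraphs.
#' 6. Optional power-law diagnostics per subgraph degree distribution.
#' 7. KCS table.
#'
#' The run is deterministic given the inputs; `seed` feeds the optional
#' bootstrap stage.
#'
#' @param microbiome Genus-level count [feature_table()].
#' @param metabolome Metabolite [feature_table()] (raw scale, `NA` missing).
#' @param metadata Sample metadata with `Sample`, `Subject`,
#'   `Treatment_Condition` columns.
#' @param q_threshold Association significance threshold (default 0.05).
#' @param max_missing_fraction,min_total_reads,min_sample_presence,pseudocount
#'   Preprocessing parameters (see the preprocessing functions).
#' @param do_power_law Run power-law fitting/bootstraps per subgraph
#'   (default `FALSE`; the fit needs enough nodes).
#' @param n_boot Bootstrap iterations when `do_power_law` (default 1000).
#' @param seed Seed for the bootstrap stage.
#' @return A list with elements `metabolome`, `microbiome` (preprocessed,
#'   transformed tables), `differential`, `da_metabolites`, `records`
#'   (associations with q), `graph`, `subgraphs`, `centralities`, `mcode`,
#'   `power_law` (or `NULL`), `kcs`, `log` (character vector of stage lines).
#' @export
run_pipeline <- function(microbiome, metabolome, metadata, q_threshold = 0.05,
                         max_missing_fraction = 0.70, min_total_reads = 1000,
                         min_sample_presence = 2, pseudocount = 1,
                         do_power_law = FALSE, n_boot = 1000, seed = 1L) {
  log_lines <- character(0)
  say <- function(...) log_lines <<- c(log_lines, sprintf(...))

  ## 1. metabolite preprocessing
  met_f <- filter_metabolites(metabolome, max_missing_fraction)
  met_s <- impute_and_median_scale(met_f)
  met_log <- log2_pseudo(met_s, pseudocount)
  say("metabolites: %d -> %d features after missingness filter (> %.0f%% removed)",
      ncol(metabolome$values), ncol(met_f$values), 100 * max_missing_fraction)

  ## 2. microbiome preprocessing
  mic_f <- filter_microbiome(microbiome, min_sample_presence, min_total_reads)
  mic_rel <- relative_abundance(mic_f)
  mic_t <- arcsine_sqrt(mic_rel)
  say("microbiome: %d -> %d features, %d -> %d samples (presence >= %d, reads >= %d)",
      ncol(microbiome$values), ncol(mic_f$values),
      nrow(microbiome$values), nrow(mic_f$values),
      min_sample_presence, min_total_reads)

  ## 3. differential metabolites on all samples
  diff <- lmm_differential(met_log, metadata)
  da <- unique(diff$metabolite[diff$significant])
  say("differential: %d DA metabolites at q < 0.05", length(da))

  ## 4. correlation stage on the read-depth-passing samples only
  shared <- intersect(sample_ids(mic_t), sample_ids(met_log))
  mic_c <- ft_subset(mic_t, samples = shared)
  met_c <- ft_subset(met_log, samples = shared)
  say("correlation stage: %d samples shared after read-depth exclusion",
      length(shared))
  res_mic <- residualize(mic_c, metadata)
  res_met <- residualize(met_c, metadata)
  sp_mm <- spearman_all_pairs(res_met)
  sp_bb <- spearman_all_pairs(res_mic)
  sp_bm <- spearman_all_pairs(res_mic, res_met)
  records <- rbind(association_records(sp_mm, "met-met"),
                   association_records(sp_bb, "bact-bact"),
                   association_records(sp_bm, "bact-met"))
  records <- adjust_fdr(records, alpha = q_threshold)
  for (fam in c("met-met", "bact-bact", "bact-met"))
    say("associations [%s]: %d significant of %d tested at q < %.2f", fam,
        sum(records$significant[records$pair_type == fam]),
        sum(records$pair_type == fam), q_threshold)

  ## 5. graph, centralities, MCODE
  g <- build_graph(records, q_threshold, da_metabolites = da)
  subgraphs <- list()
  cents <- list()
  clusters <- list("bact-bact" = list(), "bact-met" = list())
  for (pt in c("met-met", "bact-met", "bact-bact")) {
    if (igraph::ecount(g) == 0) break
    sg <- subgraph_by_type(g, pt)
    if (igraph::vcount(sg) == 0) next
    subgraphs[[pt]] <- sg
    cents[[pt]] <- centralities(sg)
    if (pt != "met-met") clusters[[pt]] <- mcode(sg)
  }
  say("graph: %d nodes, %d edges; MCODE clusters bb=%d bm=%d",
      igraph::vcount(g), igraph::ecount(g),
      length(clusters[["bact-bact"]]), length(clusters[["bact-met"]]))

  ## 6. optional power-law diagnostics
  pl <- NULL
  if (do_power_law) {
    pl <- lapply(names(subgraphs), function(pt) {
      deg <- degree_distribution_counts(subgraphs[[pt]])
      fit <- tryCatch(fit_power_law(deg), error = function(e) NULL)
      if (is.null(fit)) return(NULL)
      fit <- bootstrap_gof(fit, n_boot = n_boot, seed = seed)
      list(pair_type = pt, fit = fit,
           comparisons = tryCatch(compare_distributions(fit),
                                  warning = function(w) NULL))
    })
    names(pl) <- names(subgraphs)
  }

  ## 7. KCS
  bm_edges <- records[records$significant & records$pair_type == "bact-met",
                      c("feature_x", "feature_y"), drop = FALSE]
  kcs <- kcs_table(cent_bb = cents[["bact-bact"]], cent_bm = cents[["bact-met"]],
                   clusters_bb = clusters[["bact-bact"]],
                   clusters_bm = clusters[["bact-met"]],
                   bact_met_edges = bm_edges, da_metabolites = da)
  say("kcs: %d genera scored; top = %s", nrow(kcs),
      if (nrow(kcs)) kcs$genus[1] else "<none>")

  list(metabolome = met_log, microbiome = mic_t, differential = diff,
       da_metabolites = da, records = records, graph = g,
       subgraphs = subgraphs, centralities = cents, mcode = clusters,
       power_law = pl, kcs = kcs, log = log_lines)
}

#' Write every pipeline artifact to a directory
#'
#' Materializes the outputs of [run_pipeline()] as plain-text files:
#' associations TSV, differential TSV, GraphML, MCODE TSVs, KCS TSV, power-law
#' JSONs and the run log.
#'
#' @param result [run_pipeline()] output.
#' @param outdir Output directory (created if absent).
#' @return `outdir`, invisibly.
#' @export
write_pipeline_outputs <- function(result, outdir) {
  dir.create(outdir, recursive = TRUE, showWarnings = FALSE)
  p <- function(f) file.path(outdir, f)
  write_associations(result$records, p("associations.tsv"))
  utils::write.table(result$differential, p("differential_metabolites.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE)
  if (igraph::vcount(result$graph) > 0) write_graphml(result$graph, p("network.graphml"))
  write_mcode_clusters(result$mcode[["bact-bact"]], p("mcode_bact_bact.tsv"))
  write_mcode_clusters(result$mcode[["bact-met"]], p("mcode_bact_met.tsv"))
  write_kcs_table(result$kcs, p("kcs_table.tsv"))
  if (!is.null(result$power_law)) {
    for (pt in names(result$power_law)) {
      x <- result$power_law[[pt]]
      if (!is.null(x))
        write_power_law_json(x$fit, x$comparisons,
                             p(sprintf("power_law_%s.json", gsub("-", "_", pt))))
    }
  }
  writeLines(result$log, p("pipeline.log"))
  invisible(outdir)
}
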