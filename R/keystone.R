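# Keystone Candidate Score (KCS): a composite integer score per genus,
# aggregating MCODE cluster status, the number of distinct differentially
# abundant metabolite partners, raw degree in the bacteria-bacteria and
# bacteria-metabolite subgraphs, and HiLo betweenness bonuses.

#' MCODE cluster-status score
#'
#' Ternary score per node: 10 for an MCODE cluster seed, 5 for a non-seed
#' member, 0 otherwise. When clusters from several subgraphs are supplied, the
#' maximum across them is taken.
#'
#' @param clusters List of cluster lists as returned by [mcode()] (may
#'   concatenate clusters of several subgraphs).
#' @param node Node name.
#' @param in_graph Logical: is the node present in the graph(s)? An absent
#'   node scores 0 with a warning.
#' @return Integer in `{0, 5, 10}`.
#' @export
mcode_status_score <- function(clusters, node, in_graph = TRUE) {
  if (!in_graph) {
    warning(sprintf("node `%s` absent from the graph; MCODE status 0", node))
    return(0L)
  }
  score <- 0L
  for (cl in clusters) {
    if (identical(cl$seed, node)) score <- max(score, 10L)
    else if (node %in% cl$members) score <- max(score, 5L)
  }
  score
}

#' Count distinct differentially abundant metabolite partners
#'
#' @param bact_met_edges Data frame of significant bacteria-metabolite edges
#'   with columns `feature_x` (bacterium) and `feature_y` (metabolite).
#' @param da_metabolites Character vector of DA metabolites (q < 0.05 in the
#'   differential stage).
#' @return Named integer vector: per genus, the number of DISTINCT DA
#'   metabolites adjacent to it (genera with no edges are absent).
#' @export
count_da_partners <- function(bact_met_edges, da_metabolites) {
  if (nrow(bact_met_edges) == 0L) return(stats::setNames(integer(0), character(0)))
  ed <- unique(bact_met_edges[, c("feature_x", "feature_y")])
  ed <- ed[ed$feature_y %in% da_metabolites, , drop = FALSE]
  tab <- table(factor(ed$feature_x, levels = unique(bact_met_edges$feature_x)))
  stats::setNames(as.integer(tab), names(tab))
}

#' HiLo betweenness bonus
#'
#' Awards 3 points to the nodes with the three highest and the three lowest
#' betweenness centralities of a subgraph's largest connected component (all
#' node types compete for the slots). Ties at a slot boundary are broken by
#' higher degree, then higher closeness, then lexicographic node name. When
#' the LCC has 6 or fewer nodes every LCC node qualifies (flagged via the
#' `"small_lcc"` attribute); nodes outside the LCC score 0.
#'
#' @param cent Centrality table from [centralities()] for one subgraph.
#' @return Named integer vector over all nodes of the table, values in
#'   `{0, 3}`.
#' @export
hilo_scores <- function(cent) {
  sc <- stats::setNames(rep(0L, nrow(cent)), cent$node)
  lcc <- cent[cent$in_lcc & !is.na(cent$betweenness), , drop = FALSE]
  small <- nrow(lcc) <= 6
  if (nrow(lcc) == 0L) return(sc)
  hi <- order(-lcc$betweenness, -lcc$degree, -lcc$closeness, lcc$node)
  lo <- order(lcc$betweenness, -lcc$degree, -lcc$closeness, lcc$node)
  pick <- unique(c(lcc$node[utils::head(hi, 3)], lcc$node[utils::head(lo, 3)]))
  sc[pick] <- 3L
  attr(sc, "small_lcc") <- small
  sc
}

#' Aggregate the six KCS subcomponents
#'
#' `KCS = mcode_status + diff_metab + degree_bb + degree_bm + hilo_bb +
#' hilo_bm`, an integer.
#'
#' @param mcode_status Integer in `{0, 5, 10}`.
#' @param diff_metab Count of distinct DA metabolite partners.
#' @param degree_bb,degree_bm Raw degree in the bacteria-bacteria and
#'   bacteria-metabolite subgraphs.
#' @param hilo_bb,hilo_bm HiLo betweenness bonuses in `{0, 3}`.
#' @return Integer KCS (vectorized over the inputs).
#' @export
aggregate_kcs <- function(mcode_status, diff_metab, degree_bb, degree_bm,
                          hilo_bb, hilo_bm) {
  args <- list(mcode_status, diff_metab, degree_bb, degree_bm, hilo_bb, hilo_bm)
  if (any(vapply(args, function(a) any(is.na(a)), TRUE)))
    stop("missing subcomponent")
  as.integer(mcode_status + diff_metab + degree_bb + degree_bm +
               hilo_bb + hilo_bm)
}

#' Rank a KCS table
#'
#' Descending by KCS; ties broken by total degree (`degree_bb + degree_bm`)
#' descending, then lexicographic genus name.
#'
#' @param records Data frame with columns `genus`, `kcs`, `degree_bb`,
#'   `degree_bm` (and any others).
#' @param top_n Optional cap on the number of returned rows.
#' @return The reordered data frame with a `rank` column prepended.
#' @export
rank_kcs <- function(records, top_n = NULL) {
  o <- order(-records$kcs, -(records$degree_bb + records$degree_bm),
             records$genus)
  out <- records[o, , drop = FALSE]
  out <- cbind(rank = seq_len(nrow(out)), out)
  rownames(out) <- NULL
  if (!is.null(top_n)) out <- utils::head(out, top_n)
  out
}

#' Compute the full KCS table from network artifacts
#'
#' Combines MCODE clusters (bacteria-bacteria and bacteria-metabolite
#' subgraphs), the significant bacteria-metabolite edge list, the DA
#' metabolite set, and the two subgraphs' centrality tables into one KCS
#' record per genus. Metabolite nodes compete for HiLo slots in the
#' bacteria-metabolite subgraph but never receive records.
#'
#' @param cent_bb,cent_bm Centrality tables from [centralities()] for the
#'   bacteria-bacteria and bacteria-metabolite subgraphs (either may be `NULL`
#'   when the subgraph is empty).
#' @param clusters_bb,clusters_bm [mcode()] output per subgraph.
#' @param bact_met_edges Significant bacteria-metabolite edges (`feature_x` =
#'   bacterium).
#' @param da_metabolites Character vector of DA metabolites.
#' @return Data frame with one row per genus appearing in either subgraph:
#'   `genus`, `kcs`, `mcode_status`, `diff_metab`, `degree_bb`, `degree_bm`,
#'   `hilo_bb`, `hilo_bm`, ranked by [rank_kcs()].
#' @export
kcs_table <- function(cent_bb = NULL, cent_bm = NULL, clusters_bb = list(),
                      clusters_bm = list(), bact_met_edges = NULL,
                      da_metabolites = character(0)) {
  bb_genera <- if (!is.null(cent_bb)) cent_bb$node else character(0)
  bm_genera <- if (!is.null(cent_bm))
    cent_bm$node[cent_bm$node_type == "bacterium"] else character(0)
  genera <- sort(unique(c(bb_genera, bm_genera)))
  if (!length(genera))
    return(data.frame(rank = integer(0), genus = character(0), kcs = integer(0)))
  hilo_bb <- if (!is.null(cent_bb)) hilo_scores(cent_bb) else integer(0)
  hilo_bm <- if (!is.null(cent_bm)) hilo_scores(cent_bm) else integer(0)
  da_count <- if (!is.null(bact_met_edges))
    count_da_partners(bact_met_edges, da_metabolites) else integer(0)
  clusters <- c(clusters_bb, clusters_bm)
  get0i <- function(v, nm) if (nm %in% names(v)) as.integer(v[[nm]]) else 0L
  deg_of <- function(cent, nm) {
    if (is.null(cent)) return(0L)
    i <- match(nm, cent$node)
    if (is.na(i)) 0L else as.integer(cent$degree[i])
  }
  rows <- lapply(genera, function(gn) {
    ms <- mcode_status_score(clusters, gn)
    dm <- get0i(da_count, gn)
    dbb <- deg_of(cent_bb, gn)
    dbm <- deg_of(cent_bm, gn)
    hbb <- get0i(hilo_bb, gn)
    hbm <- get0i(hilo_bm, gn)
    data.frame(genus = gn, kcs = aggregate_kcs(ms, dm, dbb, dbm, hbb, hbm),
               mcode_status = ms, diff_metab = dm, degree_bb = dbb,
               degree_bm = dbm, hilo_bb = hbb, hilo_bm = hbm,
               stringsAsFactors = FALSE)
  })
  rank_kcs(do.call(rbind, rows))
}
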