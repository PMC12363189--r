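#' Build the typed association network from significant records
#'
#' One node per feature appearing in at least one significant association, one
#' undirected edge per significant record, weighted by rho and tagged with its
#' pair type. Node types are inferred from the pair types (`feature_x` of
#' bact-met records is the bacterium); the bact-met subgraph is bipartite by
#' construction.
#'
#' @param records Data frame from [adjust_fdr()] (columns `feature_x`,
#'   `feature_y`, `pair_type`, `rho`, `q`, `significant`).
#' @param q_threshold Edges with `q < q_threshold` are kept (default 0.05).
#' @param da_metabolites Optional character vector of differentially abundant
#'   metabolites, stored as a logical `da` node attribute.
#' @return An [igraph::graph] with node attributes `name`, `node_type`, `da`
#'   and edge attributes `rho`, `sign`, `pair_type`.
#' @export
build_graph <- function(records, q_threshold = 0.05, da_metabolites = NULL) {
  sig <- records[!is.na(records$q) & records$q < q_threshold, , drop = FALSE]
  if (nrow(sig) == 0L)
    return(igraph::make_empty_graph(n = 0, directed = FALSE))
  type_of <- function(feat, pt, is_x) {
    ifelse(pt == "bact-bact", "bacterium",
           ifelse(pt == "met-met", "metabolite",
                  ifelse(is_x, "bacterium", "metabolite")))
  }
  nodes <- rbind(
    data.frame(name = sig$feature_x,
               node_type = type_of(sig$feature_x, sig$pair_type, TRUE)),
    data.frame(name = sig$feature_y,
               node_type = type_of(sig$feature_y, sig$pair_type, FALSE)))
  nodes <- unique(nodes)
  if (anyDuplicated(nodes$name))
    stop("feature appears with conflicting node types")
  nodes <- nodes[order(nodes$name), , drop = FALSE]
  nodes$da <- nodes$name %in% (da_metabolites %||% character(0))
  g <- igraph::graph_from_data_frame(
    data.frame(from = sig$feature_x, to = sig$feature_y,
               rho = sig$rho, sign = ifelse(sig$rho >= 0, 1, -1),
               pair_type = sig$pair_type, stringsAsFactors = FALSE),
    directed = FALSE, vertices = nodes)
  if (igraph::any_multiple(g)) stop("duplicate association records")
  if (any(igraph::which_loop(g))) stop("self-loop in association records")
  g
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Extract a pair-type subgraph
#'
#' Keeps only the edges of the requested type and the nodes incident to them.
#'
#' @param g Graph from [build_graph()].
#' @param pair_type One of `"met-met"`, `"bact-met"`, `"bact-bact"`.
#' @return The induced subgraph.
#' @export
subgraph_by_type <- function(g, pair_type = c("met-met", "bact-met", "bact-bact")) {
  pair_type <- match.arg(pair_type)
  keep <- which(igraph::edge_attr(g, "pair_type") == pair_type)
  igraph::subgraph_from_edges(g, igraph::E(g)[keep], delete.vertices = TRUE)
}

#' Node centralities and graph density
#'
#' Degree is the raw incident-edge count. Betweenness is shortest-path
#' betweenness computed on the largest connected component only (unweighted
#' paths), normalized by `(n-1)(n-2)/2`; nodes outside the LCC get `NA`.
#' Closeness is the inverse mean shortest-path distance within each node's own
#' component (`NA` for isolated or 1-node components). The graph density
#' `2|E| / (|V|(|V|-1))` is attached as attribute `"density"`.
#'
#' @param g An undirected [igraph::graph].
#' @return Data frame with `node`, `node_type` (when present), `degree`,
#'   `betweenness`, `closeness`, `component_id`, `in_lcc`.
#' @export
centralities <- function(g) {
  if (igraph::vcount(g) == 0L) stop("graph is empty")
  comp <- igraph::components(g)
  lcc_id <- which.max(comp$csize)
  nm <- igraph::V(g)$name %||% as.character(seq_len(igraph::vcount(g)))
  out <- data.frame(node = nm,
                    node_type = igraph::V(g)$node_type %||% NA_character_,
                    degree = as.numeric(igraph::degree(g)),
                    betweenness = NA_real_, closeness = NA_real_,
                    component_id = comp$membership, stringsAsFactors = FALSE)
  out$in_lcc <- comp$membership == lcc_id
  lcc <- igraph::induced_subgraph(g, which(out$in_lcc))
  if (igraph::vcount(lcc) > 2) {
    bw <- igraph::betweenness(lcc, directed = FALSE, normalized = TRUE,
                              weights = NA)
    out$betweenness[match(igraph::V(lcc)$name, out$node)] <- bw
  } else if (igraph::vcount(lcc) >= 1) {
    out$betweenness[out$in_lcc] <- 0
  }
  for (cid in seq_len(comp$no)) {
    idx <- which(comp$membership == cid)
    if (length(idx) < 2) next
    sub <- igraph::induced_subgraph(g, idx)
    cl <- igraph::closeness(sub, normalized = TRUE, weights = NA)
    out$closeness[match(igraph::V(sub)$name, out$node)] <- cl
  }
  attr(out, "density") <- igraph::edge_density(g)
  rownames(out) <- NULL
  out
}

#' Degree multiset of a graph
#'
#' @param g An [igraph::graph] with at least one node.
#' @return Named integer vector, one entry per node.
#' @export
degree_distribution_counts <- function(g) {
  if (igraph::vcount(g) == 0L) stop("graph is empty")
  deg <- igraph::degree(g)
  names(deg) <- igraph::V(g)$name %||% as.character(seq_along(deg))
  deg
}

# internal: MCODE vertex weights. For each vertex with degree >= degree_cutoff,
# the weight is k_max(N[v]) * density(N[v]) where k_max is the highest k-core
# level of the closed-neighborhood subgraph and density is that subgraph's
# edge density. Penalizing the full neighborhood (rather than its core alone)
# down-weights vertices that sit at the periphery of a dense region, which is
# what lets bridges between two dense complexes break the expansion.
mcode_weights <- function(g, degree_cutoff) {
  n <- igraph::vcount(g)
  w <- numeric(n)
  deg <- igraph::degree(g)
  for (v in seq_len(n)) {
    if (deg[v] < degree_cutoff) next
    nb <- c(v, as.integer(igraph::neighbors(g, v)))
    sub <- igraph::induced_subgraph(g, nb)
    k <- max(igraph::coreness(sub))
    w[v] <- k * igraph::edge_density(sub)
  }
  w
}

#' MCODE molecular-complex detection
#'
#' Deterministic reimplementation of the MCODE graph-clustering algorithm:
#' (1) vertex weighting by local density (see Details); (2) complex
#' prediction seeded at the highest-weight unused vertex, with breadth-first
#' inclusion of neighbors whose weight is at least
#' `seed_weight * (1 - node_score_cutoff)`, up to `max_depth` steps from the
#' seed; (3) post-processing that discards complexes lacking a 2-core and
#' (with `haircut`) strips singly-connected periphery. Complexes are
#' node-disjoint (`fluff` off). Ties in vertex weight are broken by
#' lexicographic node name, making the output invariant to node insertion
#' order.
#'
#' @details The weight of a vertex is `k * density` of its closed-neighborhood
#' subgraph, where `k` is the subgraph's highest k-core level; vertices with
#' degree below `degree_cutoff` weigh 0.
#'
#' @param g Simple undirected [igraph::graph].
#' @param degree_cutoff Minimum degree for a non-zero weight (default 2).
#' @param node_score_cutoff Fractional weight tolerance for complex expansion
#'   (default 0.2).
#' @param k_core Core level a surviving complex must contain (default 2).
#' @param haircut Remove singly-connected vertices from complexes
#'   (default `TRUE`).
#' @param max_depth Maximum expansion distance from the seed (default 100).
#' @return List of clusters, each a list with `members` (node names), `seed`
#'   and `score` (density x size); sorted by score descending.
#' @export
mcode <- function(g, degree_cutoff = 2, node_score_cutoff = 0.2, k_core = 2,
                  haircut = TRUE, max_depth = 100) {
  n <- igraph::vcount(g)
  if (n == 0L) return(list())
  if (is.null(igraph::V(g)$name))
    g <- igraph::set_vertex_attr(g, "name", value = as.character(seq_len(n)))
  nm <- igraph::V(g)$name
  w <- mcode_weights(g, degree_cutoff)
  used <- rep(FALSE, n)
  complexes <- list()
  for (seed in order(-w, nm)) {
    if (used[seed]) next
    thr <- w[seed] * (1 - node_score_cutoff)
    members <- seed
    used[seed] <- TRUE
    frontier <- seed
    depth <- 0L
    while (length(frontier) && depth < max_depth) {
      nxt <- integer(0)
      for (v in frontier) {
        for (u in as.integer(igraph::neighbors(g, v))) {
          if (!used[u] && w[u] >= thr) {
            used[u] <- TRUE
            members <- c(members, u)
            nxt <- c(nxt, u)
          }
        }
      }
      frontier <- nxt
      depth <- depth + 1L
    }
    complexes[[length(complexes) + 1L]] <- list(seed = seed, members = members)
  }
  ## post-processing
  out <- list()
  for (cx in complexes) {
    sub <- igraph::induced_subgraph(g, cx$members)
    core <- igraph::coreness(sub)
    if (max(core) < k_core) next
    keep <- igraph::V(sub)$name
    if (haircut) keep <- igraph::V(sub)$name[core >= 2]
    if (length(keep) < 2) next
    sub2 <- igraph::induced_subgraph(g, match(keep, nm))
    ## keep the component containing the seed (or the largest one)
    comp <- igraph::components(sub2)
    seed_name <- nm[cx$seed]
    cid <- if (seed_name %in% igraph::V(sub2)$name)
      comp$membership[[seed_name]] else which.max(comp$csize)
    keep <- igraph::V(sub2)$name[comp$membership == cid]
    sub3 <- igraph::induced_subgraph(g, match(keep, nm))
    out[[length(out) + 1L]] <- list(
      members = sort(keep), seed = seed_name,
      score = igraph::edge_density(sub3) * length(keep))
  }
  if (!length(out)) return(list())
  o <- order(-vapply(out, `[[`, 0, "score"),
             -vapply(out, function(x) length(x$members), 0L),
             vapply(out, `[[`, "", "seed"))
  out[o]
}
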