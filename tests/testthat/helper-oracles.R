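# Independent brute-force oracles used across the suite. These deliberately
# avoid the code paths of the implementation they check.

# Benjamini-Hochberg step-up, written from the definition:
# q_(i) = min_{j >= i} ( m * p_(j) / j ), mapped back to input order.
bf_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  q_sorted <- m * p[o] / seq_len(m)
  q_sorted <- rev(cummin(rev(q_sorted)))
  q <- numeric(m)
  q[o] <- pmin(q_sorted, 1)
  q
}

# Spearman rho from the no-ties rank formula 1 - 6*sum(d^2)/(n(n^2-1)).
bf_spearman <- function(x, y) {
  d <- rank(x) - rank(y)
  n <- length(x)
  1 - 6 * sum(d^2) / (n * (n^2 - 1))
}

# Normalized betweenness by explicit enumeration of all shortest paths
# (adjacency matrix input; feasible for <= 12 nodes).
bf_betweenness <- function(adj) {
  n <- nrow(adj)
  # all-pairs shortest path lengths by BFS
  dists <- matrix(Inf, n, n)
  for (s in seq_len(n)) {
    dist <- rep(Inf, n); dist[s] <- 0
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) for (u in which(adj[v, ] > 0))
        if (dist[u] > dist[v] + 1) { dist[u] <- dist[v] + 1; nxt <- c(nxt, u) }
      frontier <- unique(nxt)
    }
    dists[s, ] <- dist
  }
  # enumerate all shortest paths recursively
  paths_between <- function(s, t) {
    if (s == t) return(list(s))
    preds <- which(adj[, t] > 0 & dists[s, ] == dists[s, t] - 1)
    out <- list()
    for (p in preds) for (pp in paths_between(s, p))
      out[[length(out) + 1L]] <- c(pp, t)
    out
  }
  bw <- numeric(n)
  for (s in seq_len(n - 1)) for (t in (s + 1):n) {
    if (!is.finite(dists[s, t])) next
    ps <- paths_between(s, t)
    for (pth in ps) {
      inner <- setdiff(pth, c(s, t))
      bw[inner] <- bw[inner] + 1 / length(ps)
    }
  }
  if (n > 2) bw / ((n - 1) * (n - 2) / 2) else bw
}

# Discrete power-law MLE by plain grid search (independent of optimize()),
# zeta evaluated by direct long summation.
bf_dpl_alpha <- function(x, xmin, grid = seq(1.1, 6, by = 0.001)) {
  zeta_long <- function(a) sum((xmin:(xmin + 2e5))^(-a))
  ll <- vapply(grid, function(a) -length(x) * log(zeta_long(a)) - a * sum(log(x)),
               0)
  grid[which.max(ll)]
}

# small feature_table builders
make_ft <- function(values, type = "metabolome", panel = NULL, genus = NULL) {
  if (is.null(colnames(values)))
    colnames(values) <- sprintf("F%02d", seq_len(ncol(values)))
  if (is.null(rownames(values)))
    rownames(values) <- sprintf("S%02d", seq_len(nrow(values)))
  fm <- data.frame(feature = colnames(values), stringsAsFactors = FALSE)
  if (!is.null(panel)) fm$panel <- panel
  if (!is.null(genus)) fm$genus <- genus
  feature_table(values, fm, type = type)
}

# igraph toy builders (edge list by name)
toy_graph <- function(edges) {
  igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2], stringsAsFactors = FALSE),
    directed = FALSE)
}

clique_edges <- function(nodes) {
  t(utils::combn(nodes, 2))
}
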