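# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths (and igraph) so agreement is meaningful.

# Brute-force betweenness by BFS path counting on an undirected edge list.
# nodes: character vector; edges: data.frame(node_a, node_b).
# Returns the normalized betweenness (divided by (n-1)(n-2)/2), named.
brute_force_betweenness <- function(nodes, edges) {
  n <- length(nodes)
  idx <- setNames(seq_len(n), nodes)
  adj <- vector("list", n)
  for (i in seq_len(nrow(edges))) {
    a <- idx[[edges$node_a[i]]]; b <- idx[[edges$node_b[i]]]
    adj[[a]] <- union(adj[[a]], b)
    adj[[b]] <- union(adj[[b]], a)
  }
  dist <- matrix(Inf, n, n)
  npath <- matrix(0, n, n)
  for (s in seq_len(n)) {
    d <- rep(Inf, n); np <- rep(0, n)
    d[s] <- 0; np[s] <- 1
    frontier <- s
    while (length(frontier)) {
      nxt <- integer(0)
      for (v in frontier) {
        for (w in adj[[v]]) {
          if (is.infinite(d[w])) {
            d[w] <- d[v] + 1
            nxt <- union(nxt, w)
          }
          if (d[w] == d[v] + 1) np[w] <- np[w] + np[v]
        }
      }
      frontier <- nxt
    }
    dist[s, ] <- d
    npath[s, ] <- np
  }
  btw <- setNames(numeric(n), nodes)
  for (v in seq_len(n)) {
    acc <- 0
    for (s in seq_len(n - 1)) {
      for (t in (s + 1):n) {
        if (s == v || t == v || is.infinite(dist[s, t])) next
        if (dist[s, v] + dist[v, t] == dist[s, t]) {
          acc <- acc + npath[s, v] * npath[v, t] / npath[s, t]
        }
      }
    }
    btw[v] <- acc
  }
  if (n > 2) btw / ((n - 1) * (n - 2) / 2) else btw * 0
}

# Exhaustive hypergeometric upper tail: probability that a uniformly drawn
# size-k subset of a size-N universe hits >= x of the K marked elements,
# by enumerating every subset.
enum_hypergeom_tail <- function(N, K, k, x) {
  draws <- utils::combn(N, k)
  marked <- seq_len(K)
  hits <- apply(draws, 2, function(col) sum(col %in% marked))
  mean(hits >= x)
}

# Erdos-Renyi-ish random connected-enough test graph as an edge data.frame.
random_edges <- function(n, p = 0.35) {
  nodes <- sprintf("n%02d", seq_len(n))
  pairs <- utils::combn(n, 2)
  keep <- stats::runif(ncol(pairs)) < p
  # guarantee at least one edge so the graph is non-degenerate
  if (!any(keep)) keep[1] <- TRUE
  data.frame(node_a = nodes[pairs[1, keep]],
             node_b = nodes[pairs[2, keep]],
             score = 900, stringsAsFactors = FALSE)
}

# Small default study used by several module tests.
small_study <- function(seed = 101L, ...) {
  generate_study(simulation_config(
    n_genes = 200L, n_disease_genes = 40L, n_per_group = 5L,
    ppi_edges_per_node = 5L, seed = seed, ...
  ))
}
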