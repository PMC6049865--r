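# Shared fixtures and independent oracles used across the suite.

# Small labelled matrix builder
toy_matrix <- function(nr, nc, seed = 1, prefix = "f") {
  set.seed(seed)
  matrix(rnorm(nr * nc), nr, nc,
         dimnames = list(paste0(prefix, seq_len(nr)),
                         paste0("s", seq_len(nc))))
}

edge_adjacency <- function(edges) {
  adj <- list()
  add <- function(a, b) adj[[a]] <<- unique(c(adj[[a]], b))
  for (i in seq_len(nrow(edges))) {
    if (edges[i, 1] == edges[i, 2]) next
    add(edges[i, 1], edges[i, 2])
    add(edges[i, 2], edges[i, 1])
  }
  adj
}

# Hand-rolled BFS hop distance between two nodes; Inf when disconnected
bfs_distance <- function(adj, from, to) {
  if (from == to) return(0)
  dist <- c(stats::setNames(0, from))
  frontier <- from
  while (length(frontier)) {
    nxt <- character(0)
    for (node in frontier) {
      for (nb in adj[[node]]) {
        if (!nb %in% names(dist)) {
          dist[nb] <- dist[[node]] + 1
          if (nb == to) return(dist[[nb]])
          nxt <- c(nxt, nb)
        }
      }
    }
    frontier <- nxt
  }
  Inf
}

# Enumerate ALL simple paths of length <= cutoff between two nodes by
# depth-limited DFS; with cutoff = shortest distance this yields exactly
# the minimal paths. Pure R, used as the brute-force oracle for the
# shortest-path union.
all_simple_paths_bf <- function(edges, from, to, cutoff) {
  adj <- edge_adjacency(edges)
  paths <- list()
  walk <- function(node, seen) {
    if (node == to) {
      paths[[length(paths) + 1]] <<- seen
      return(invisible())
    }
    if (length(seen) > cutoff) return(invisible())
    for (nb in adj[[node]])
      if (!nb %in% seen) walk(nb, c(seen, nb))
  }
  if (!is.null(adj[[from]])) walk(from, from)
  paths
}

# Brute-force union of minimal-length paths over all seed pairs: returns
# sorted node ids and sorted canonical edge keys "a|b" (a < b).
shortest_union_bf <- function(edges, seeds) {
  nodes <- character(0)
  ekeys <- character(0)
  seeds <- sort(unique(seeds))
  if (length(seeds) == 1) return(list(nodes = seeds, edges = character(0)))
  adj <- edge_adjacency(edges)
  for (i in seq_len(length(seeds) - 1)) {
    for (j in seq(i + 1, length(seeds))) {
      d <- bfs_distance(adj, seeds[i], seeds[j])
      if (!is.finite(d)) next
      ps <- all_simple_paths_bf(edges, seeds[i], seeds[j], cutoff = d)
      lens <- vapply(ps, length, integer(1))
      for (p in ps[lens == min(lens)]) {
        nodes <- c(nodes, p)
        if (length(p) > 1) {
          lo <- pmin(p[-length(p)], p[-1]); hi <- pmax(p[-length(p)], p[-1])
          ekeys <- c(ekeys, paste(lo, hi, sep = "|"))
        }
      }
    }
  }
  list(nodes = sort(unique(c(nodes, seeds))),
       edges = sort(unique(ekeys)))
}

# Canonical edge keys of an igraph, for comparison with the oracle
graph_edge_keys <- function(g) {
  el <- igraph::as_edgelist(g)
  if (nrow(el) == 0) return(character(0))
  sort(paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]), sep = "|"))
}

# Random connected-ish small graph as an edge list (character matrix)
random_edgelist <- function(n_nodes, p_edge, seed) {
  set.seed(seed)
  ids <- sprintf("n%02d", seq_len(n_nodes))
  pairs <- t(utils::combn(ids, 2))
  keep <- runif(nrow(pairs)) < p_edge
  # ensure no isolated graph: add a random spanning chain
  chain <- cbind(ids[-n_nodes], ids[-1])
  rbind(pairs[keep, , drop = FALSE], chain)
}

# Adjusted Rand index between two labelings
adjusted_rand <- function(a, b) {
  tab <- table(a, b)
  comb2 <- function(x) x * (x - 1) / 2
  sum_ij <- sum(comb2(tab))
  sum_a <- sum(comb2(rowSums(tab)))
  sum_b <- sum(comb2(colSums(tab)))
  n <- comb2(sum(tab))
  expected <- sum_a * sum_b / n
  (sum_ij - expected) / ((sum_a + sum_b) / 2 - expected)
}

# Default synthetic cohort processed to target level; memoised per seed so
# several tests can reuse the same run cheaply.
.cohort_cache <- new.env(parent = emptyenv())
processed_cohort <- function(seed = 1, ...) {
  key <- paste0("s", seed, "_", paste(deparse(list(...)), collapse = ""))
  if (!is.null(.cohort_cache[[key]])) return(.cohort_cache[[key]])
  sim <- simulate_cohort(cohort_config(seed = seed, ...))
  nm <- glog_normalize(sim$raw)
  tg <- collapse_probes(nm$normalized, sim$annotation)
  out <- list(sim = sim, norm = nm, targets = tg)
  .cohort_cache[[key]] <- out
  out
}
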