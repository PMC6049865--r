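test_that("seed filtering requires strong evidence and the GO term", {
  targets <- data.frame(
    mirna = c("miR-1", "miR-1", "miR-2", "miR-3"),
    gene = c("G1", "G2", "G3", "G4"),
    evidence = c("strong", "weak", "strong", "strong"))
  go <- data.frame(gene = c("G1", "G2", "G3"),
                   go_id = "GO:0030098")
  seeds <- filter_targets(targets, c("miR-1", "miR-2"), go)
  expect_equal(seeds, c("G1", "G3"))  # G2 weak-only, G4 unannotated

  expect_error(filter_targets(targets, character(0), go), "non-empty")
  expect_error(filter_targets(targets, "miR-1", go, "GO:9999999"),
               "GO term")
})

test_that("seed filtering equals an exhaustive row scan on random tables", {
  set.seed(21)
  genes <- sprintf("G%03d", 1:60)
  targets <- data.frame(
    mirna = sample(sprintf("miR-%d", 1:10), 50, replace = TRUE),
    gene = sample(genes, 50, replace = TRUE),
    evidence = sample(c("strong", "weak"), 50, replace = TRUE,
                      prob = c(0.4, 0.6)))
  targets <- unique(targets)
  go <- data.frame(gene = sample(genes, 24), go_id = "GO:0030098")
  de <- sprintf("miR-%d", 1:5)
  got <- filter_targets(targets, de, go)
  want <- character(0)
  for (i in seq_len(nrow(targets)))
    if (targets$mirna[i] %in% de && targets$evidence[i] == "strong" &&
        targets$gene[i] %in% go$gene)
      want <- c(want, targets$gene[i])
  expect_equal(got, sort(unique(want)))
})

test_that("shortest-path union basics: adjacent pair, single seed", {
  g <- make_interactome(c("a", "b", "c"), c("b", "c", "d"))
  sub <- shortest_path_union(g, c("a", "b"))
  expect_setequal(igraph::V(sub)$name, c("a", "b"))
  expect_equal(igraph::ecount(sub), 1)

  single <- shortest_path_union(g, "c")
  expect_equal(igraph::V(single)$name, "c")
  expect_equal(igraph::ecount(single), 0)

  expect_error(shortest_path_union(g, "zzz"), "no seed")
  expect_warning(shortest_path_union(g, c("a", "zzz")), "dropped")
})

test_that("shortest-path union matches brute-force minimal-path enumeration", {
  for (s in 1:20) {
    edges <- random_edgelist(n_nodes = sample(8:20, 1), p_edge = 0.15,
                             seed = s)
    g <- make_interactome(edges[, 1], edges[, 2])
    set.seed(s + 500)
    seeds <- sample(igraph::V(g)$name, sample(2:4, 1))
    sub <- shortest_path_union(g, seeds)
    bf <- shortest_union_bf(edges, seeds)
    expect_equal(sort(igraph::V(sub)$name), bf$nodes)
    expect_equal(graph_edge_keys(sub), bf$edges)
  }
})

test_that("union is invariant to seed order and edge-list order", {
  edges <- random_edgelist(15, 0.2, seed = 99)
  g1 <- make_interactome(edges[, 1], edges[, 2])
  perm <- sample(nrow(edges))
  g2 <- make_interactome(edges[perm, 2], edges[perm, 1])
  seeds <- c("n01", "n07", "n12")
  a <- shortest_path_union(g1, seeds)
  b <- shortest_path_union(g2, rev(seeds))
  expect_equal(sort(igraph::V(a)$name), sort(igraph::V(b)$name))
  expect_equal(graph_edge_keys(a), graph_edge_keys(b))
})

test_that("every subnetwork node lies on a minimal seed-pair path", {
  for (s in c(3, 8)) {
    edges <- random_edgelist(12, 0.2, seed = s)
    g <- make_interactome(edges[, 1], edges[, 2])
    seeds <- c("n02", "n05", "n11")
    sub <- shortest_path_union(g, seeds)
    bf <- shortest_union_bf(edges, seeds)
    expect_true(all(igraph::V(sub)$name %in% bf$nodes))
  }
})

test_that("adding a seed-seed edge never lengthens pairwise distances", {
  edges <- random_edgelist(15, 0.15, seed = 17)
  g <- make_interactome(edges[, 1], edges[, 2])
  seeds <- c("n01", "n08", "n14")
  d_before <- igraph::distances(g, v = seeds, to = seeds)
  g2 <- igraph::add_edges(g, c("n01", "n14"))
  d_after <- igraph::distances(g2, v = seeds, to = seeds)
  expect_true(all(d_after <= d_before))
})

test_that("hub ranking: star center, ties, k overflow", {
  star <- make_interactome(rep("hub", 5), paste0("x", 1:5))
  sub <- shortest_path_union(star, paste0("x", 1:5))
  hubs <- rank_hubs(sub, k = 1)
  expect_equal(hubs$protein, "hub")

  # equal degree: lexicographically smaller id first
  square <- make_interactome(c("a", "b", "c", "d"), c("b", "c", "d", "a"))
  sq <- shortest_path_union(square, c("a", "c"))
  r <- rank_hubs(sq, k = 4)
  expect_equal(r$degree, rep(2L, 4))
  expect_equal(r$protein, c("a", "b", "c", "d"))
  expect_warning(rank_hubs(sq, k = 99), "k > node count")
})

test_that("miRNA overlay adds strong-evidence edges into the subnetwork", {
  g <- make_interactome(c("P1", "P2", "P3"), c("P2", "P3", "P4"))
  sub <- shortest_path_union(g, c("P1", "P4"))
  targets <- data.frame(
    mirna = c("miR-a", "miR-a", "miR-b", "miR-c"),
    gene = c("P2", "P9", "P3", "P2"),
    evidence = c("strong", "strong", "weak", "strong"))
  de <- data.frame(target = c("miR-a", "miR-b"), direction = c("up", "down"))
  net <- overlay_mirnas(sub, targets, de, k = 2)
  # only miR-a -> P2 qualifies (strong, DE, protein in subnetwork)
  expect_equal(nrow(net$overlay), 1)
  expect_equal(net$overlay$mirna, "mir-a")
  expect_equal(net$overlay$protein, "P2")
  expect_equal(net$overlay$direction, "up")

  none <- overlay_mirnas(sub, targets,
                         data.frame(target = "miR-z"), k = 2)
  expect_equal(nrow(none$overlay), 0)
})

test_that("connected-miRNA count equals an exhaustive table scan", {
  si <- simulate_interactome(seed = 8)
  sub <- shortest_path_union(si$graph, si$truth$seed_genes)
  hubs <- rank_hubs(sub, k = 7)
  net <- overlay_mirnas(sub, si$targets,
                        data.frame(target = si$de_mirnas), k = 7)
  # brute-force scan of the target table
  want <- character(0)
  for (i in seq_len(nrow(si$targets)))
    if (si$targets$evidence[i] == "strong" &&
        normalize_mirna_id(si$targets$mirna[i]) %in%
          normalize_mirna_id(si$de_mirnas) &&
        si$targets$gene[i] %in% hubs$protein)
      want <- c(want, normalize_mirna_id(si$targets$mirna[i]))
  expect_equal(net$n_connected_mirnas, length(unique(want)))
})
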