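#' Simulate an interactome with planted hub proteins
#'
#' Builds a reduced-scale stand-in for a global protein-protein interactome
#' together with the companion tables the network stage consumes: a
#' preferential-attachment base graph; a miRNA-target table assigning each
#' simulated miRNA 2-20 gene targets with strong/weak evidence labels; a GO
#' table marking a configurable share of genes with the filter term; and
#' `n_planted_hubs` nodes additionally wired to every seed-eligible gene
#' (strong-evidence, GO-annotated targets of the DE miRNAs), so each
#' planted hub sits on a length-2 path between every seed pair and attains
#' high degree in the shortest-path subnetwork.
#'
#' @param n_nodes proteins in the base graph (default 150).
#' @param n_planted_hubs hubs to plant (default 2; must be < n_nodes).
#' @param attach_m edges added per node in the preferential-attachment
#'   growth (default 2).
#' @param n_mirnas simulated miRNAs in the target table (default 15).
#' @param n_de_mirnas how many of them are flagged differentially
#'   expressed (default 8).
#' @param strong_prop proportion of target edges labelled strong evidence
#'   (default 0.5).
#' @param go_prop proportion of genes annotated with the filter GO term
#'   (default 0.4).
#' @param go_term the filter term id (default `GO:0030098`).
#' @param seed integer seed.
#' @return list with `graph` (igraph), `targets`, `go`, `de_mirnas`, and
#'   `truth` (`planted_hubs`, `seed_genes`).
#' @export
simulate_interactome <- function(n_nodes = 150, n_planted_hubs = 2,
                                 attach_m = 2, n_mirnas = 15,
                                 n_de_mirnas = 8, strong_prop = 0.5,
                                 go_prop = 0.4, go_term = "GO:0030098",
                                 seed = 1L) {
  if (n_planted_hubs >= n_nodes)
    stop("n_planted_hubs must be < n_nodes")
  set.seed(as.integer(seed))
  base <- igraph::sample_pa(n_nodes, m = attach_m, directed = FALSE)
  genes <- sprintf("G%04d", seq_len(n_nodes))
  igraph::V(base)$name <- genes

  mirnas <- sprintf("mir-net-%02d", seq_len(n_mirnas))
  de_mirnas <- sample(mirnas, n_de_mirnas)
  n_tg <- sample(2:20, n_mirnas, replace = TRUE)
  targets <- do.call(rbind, lapply(seq_len(n_mirnas), function(i)
    data.frame(mirna = mirnas[i],
               gene = sample(genes, n_tg[i]),
               stringsAsFactors = FALSE)))
  targets$evidence <- ifelse(stats::runif(nrow(targets)) < strong_prop,
                             "strong", "weak")
  go_genes <- sample(genes, round(go_prop * n_nodes))
  go <- data.frame(gene = go_genes, go_id = go_term,
                   stringsAsFactors = FALSE)

  seed_genes <- filter_targets(targets, de_mirnas, go, go_term)
  # planted hubs: non-seed nodes wired to every seed-eligible gene
  hub_pool <- setdiff(genes, seed_genes)
  planted <- sample(hub_pool, n_planted_hubs)
  extra <- as.vector(t(expand.grid(planted, seed_genes,
                                   stringsAsFactors = FALSE)))
  g <- base
  if (length(seed_genes) > 0 && length(planted) > 0) {
    el <- igraph::as_edgelist(g)
    have <- paste(pmin(el[, 1], el[, 2]), pmax(el[, 1], el[, 2]))
    new <- matrix(extra, ncol = 2, byrow = TRUE)
    key <- paste(pmin(new[, 1], new[, 2]), pmax(new[, 1], new[, 2]))
    new <- new[!key %in% have & !duplicated(key), , drop = FALSE]
    if (nrow(new))
      g <- igraph::add_edges(g, as.vector(t(new)))
  }
  g <- igraph::simplify(g)
  igraph::E(g)$type <- "ppi"
  list(graph = g, targets = targets, go = go, de_mirnas = de_mirnas,
       truth = list(planted_hubs = sort(planted), seed_genes = seed_genes))
}
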