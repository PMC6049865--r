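#' Build an interactome graph
#'
#' @param a,b character vectors of endpoint protein ids (parallel).
#' @return an undirected simple igraph (self-loops and duplicate edges
#'   removed), edge attribute `type = "ppi"`.
#' @export
make_interactome <- function(a, b) {
  a <- as.character(a); b <- as.character(b)
  keep <- a != b
  # canonical order so duplicates collapse regardless of orientation
  lo <- pmin(a[keep], b[keep]); hi <- pmax(a[keep], b[keep])
  dup <- duplicated(paste(lo, hi, sep = "\r"))
  g <- igraph::graph_from_edgelist(cbind(lo[!dup], hi[!dup]),
                                   directed = FALSE)
  igraph::E(g)$type <- "ppi"
  g
}

#' Seed genes: strong-evidence targets of DE miRNAs within a GO category
#'
#' Filters a miRNA-target table down to the primary target genes used to
#' seed the network: the gene must be targeted by at least one
#' differentially expressed miRNA with strong (low-throughput validated)
#' evidence, and must be annotated with the filter GO term (the study used
#' "lymphocyte differentiation", GO:0030098).
#'
#' @param targets data frame `mirna`, `gene`, `evidence` (strong/weak).
#' @param de_mirnas non-empty character vector of DE miRNA ids.
#' @param go data frame `gene`, `go_id`.
#' @param go_term GO id to filter on; must occur in `go`.
#' @return sorted character vector of seed gene ids.
#' @export
filter_targets <- function(targets, de_mirnas, go,
                           go_term = "GO:0030098") {
  if (length(de_mirnas) == 0) stop("de_mirnas must be non-empty")
  if (!go_term %in% go$go_id)
    stop("GO term not in annotation universe: ", go_term)
  de <- normalize_mirna_id(de_mirnas)
  hit <- normalize_mirna_id(targets$mirna) %in% de &
    targets$evidence == "strong"
  annotated <- unique(go$gene[go$go_id == go_term])
  sort(unique(targets$gene[hit][targets$gene[hit] %in% annotated]))
}

#' Union of all shortest paths between seed genes
#'
#' For every unordered pair of seeds present in the graph, enumerates ALL
#' unweighted shortest paths and takes the union of their nodes and edges.
#' Seeds absent from the graph are dropped with a warning, as are seed
#' pairs in different components. The result is independent of seed order
#' and of the edge-list order of the input graph.
#'
#' @param graph igraph interactome ([make_interactome()]).
#' @param seeds character vector of seed gene ids; at least one must be in
#'   the graph.
#' @return an igraph subnetwork; vertex attribute `is_seed`.
#' @export
shortest_path_union <- function(graph, seeds) {
  seeds <- sort(unique(as.character(seeds)))
  if (length(seeds) == 0) stop("seeds must be non-empty")
  present <- seeds[seeds %in% igraph::V(graph)$name]
  if (length(present) == 0) stop("no seed present in the graph")
  if (length(present) < length(seeds))
    warning("seed(s) not in graph, dropped: ",
            paste(setdiff(seeds, present), collapse = ", "))

  nodes <- present
  edge_keys <- character(0)
  if (length(present) > 1) {
    for (i in seq_len(length(present) - 1)) {
      for (j in seq(i + 1, length(present))) {
        sp <- suppressWarnings(
          igraph::all_shortest_paths(graph, from = present[i],
                                     to = present[j], mode = "all"))
        if (length(sp$res) == 0) {
          warning("seeds in different components, pair skipped: ",
                  present[i], " / ", present[j])
          next
        }
        for (pth in sp$res) {
          nm <- igraph::as_ids(pth)
          nodes <- c(nodes, nm)
          if (length(nm) > 1) {
            lo <- pmin(nm[-length(nm)], nm[-1])
            hi <- pmax(nm[-length(nm)], nm[-1])
            edge_keys <- c(edge_keys, paste(lo, hi, sep = "\r"))
          }
        }
      }
    }
  }
  nodes <- sort(unique(nodes))
  edge_keys <- sort(unique(edge_keys))
  sub <- igraph::graph_from_edgelist(
    do.call(rbind, c(list(matrix(character(0), 0, 2)),
                     strsplit(edge_keys, "\r", fixed = TRUE))),
    directed = FALSE)
  sub <- igraph::add_vertices(sub,
                              length(setdiff(nodes, igraph::V(sub)$name)),
                              name = setdiff(nodes, igraph::V(sub)$name))
  sub <- igraph::permute(sub, match(igraph::V(sub)$name,
                                    sort(igraph::V(sub)$name)))
  igraph::V(sub)$is_seed <- igraph::V(sub)$name %in% present
  igraph::E(sub)$type <- "ppi"
  sub
}

#' Rank hub proteins by degree within the subnetwork
#'
#' Hubs are the proteins of highest degree, with degree counted inside the
#' shortest-path subnetwork (the full-interactome degree can be attached as
#' an extra column via `full_graph`). Ties are broken lexicographically by
#' id; the study singled out the 7 highest-degree proteins.
#'
#' @param subnetwork igraph from [shortest_path_union()].
#' @param k number of hubs to return (default 7); if larger than the node
#'   count, all nodes are returned with a warning.
#' @param full_graph optional full interactome for the extra degree column.
#' @return data frame `protein`, `degree` (subnetwork), `rank`, optional
#'   `degree_full`.
#' @export
rank_hubs <- function(subnetwork, k = 7, full_graph = NULL) {
  n <- igraph::vcount(subnetwork)
  if (n == 0) stop("empty subnetwork")
  if (k > n) {
    warning("k > node count, returning all ", n, " nodes")
    k <- n
  }
  deg <- igraph::degree(subnetwork)
  ord <- order(-deg, names(deg))
  out <- data.frame(protein = names(deg)[ord][seq_len(k)],
                    degree = unname(deg[ord])[seq_len(k)],
                    rank = seq_len(k), stringsAsFactors = FALSE)
  if (!is.null(full_graph)) {
    fd <- igraph::degree(full_graph)
    out$degree_full <- unname(fd[out$protein])
  }
  out
}

#' Overlay differentially expressed miRNAs on the protein subnetwork
#'
#' Adds bipartite miRNA-to-protein edges for every strong-evidence target
#' pair whose protein lies in the subnetwork and whose miRNA is in the
#' differential-expression results; each overlay edge carries the miRNA's
#' regulation direction. Returns the full annotated hub network.
#'
#' @param subnetwork igraph from [shortest_path_union()].
#' @param targets miRNA-target table (`mirna`, `gene`, `evidence`).
#' @param de_results data frame with columns `target` (miRNA id) and,
#'   optionally, `direction` (up/down); every miRNA listed is treated as
#'   differentially expressed.
#' @param k hubs to flag, passed to [rank_hubs()].
#' @return object of class `hub_network`: list with `graph` (igraph with
#'   ppi + mirna_target edges; vertex attributes `node_type`, `is_seed`,
#'   `is_hub`, `degree`), `hubs` (from [rank_hubs()]), `overlay` (data
#'   frame `mirna`, `protein`, `direction`), and `n_connected_mirnas`.
#' @export
overlay_mirnas <- function(subnetwork, targets, de_results, k = 7) {
  de_ids <- normalize_mirna_id(de_results$target)
  dir <- if ("direction" %in% names(de_results))
    stats::setNames(de_results$direction, de_ids)
  else stats::setNames(rep(NA_character_, length(de_ids)), de_ids)

  prot <- igraph::V(subnetwork)$name
  tt <- targets[targets$evidence == "strong" &
                  normalize_mirna_id(targets$mirna) %in% de_ids &
                  targets$gene %in% prot, , drop = FALSE]
  overlay <- unique(data.frame(mirna = normalize_mirna_id(tt$mirna),
                               protein = tt$gene,
                               stringsAsFactors = FALSE))
  overlay <- overlay[order(overlay$mirna, overlay$protein), , drop = FALSE]
  overlay$direction <- unname(dir[overlay$mirna])

  hubs <- rank_hubs(subnetwork, k = k)
  deg_sub <- igraph::degree(subnetwork)

  g <- subnetwork
  mir_nodes <- sort(unique(overlay$mirna))
  if (length(mir_nodes))
    g <- igraph::add_vertices(g, length(mir_nodes), name = mir_nodes)
  igraph::V(g)$node_type <-
    ifelse(igraph::V(g)$name %in% mir_nodes, "mirna", "protein")
  if (nrow(overlay)) {
    g <- igraph::add_edges(
      g, as.vector(t(as.matrix(overlay[, c("mirna", "protein")]))),
      attr = list(type = rep("mirna_target", nrow(overlay)),
                  direction = overlay$direction))
  }
  isv <- igraph::V(g)$is_seed
  igraph::V(g)$is_seed <- !is.na(isv) & isv
  igraph::V(g)$is_hub <- igraph::V(g)$name %in% hubs$protein
  igraph::V(g)$degree <-
    ifelse(igraph::V(g)$name %in% names(deg_sub),
           deg_sub[igraph::V(g)$name], NA_integer_)

  structure(list(graph = g, hubs = hubs, overlay = overlay,
                 n_connected_mirnas = length(unique(
                   overlay$mirna[overlay$protein %in% hubs$protein]))),
            class = "hub_network")
}

#' @export
print.hub_network <- function(x, ...) {
  cat(sprintf(
    "<hub_network> %d nodes (%d miRNAs), %d edges; %d hub(s); %d miRNA(s) hitting hubs\n",
    igraph::vcount(x$graph),
    sum(igraph::V(x$graph)$node_type == "mirna"),
    igraph::ecount(x$graph), nrow(x$hubs), x$n_connected_mirnas))
  print(x$hubs, row.names = FALSE)
  invisible(x)
}

#' Write a hub network to GraphML
#'
#' @param net a `hub_network`.
#' @param path output path.
#' @export
write_hub_network_graphml <- function(net, path) {
  igraph::write_graph(net$graph, path, format = "graphml")
  invisible(path)
}
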