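## Gene-gene co-occurrence network: weighted adjacency from per-abstract
## gene sets, giant-component extraction, weight pruning, centralities and
## modularity communities. Graphs are igraph objects (undirected, named
## vertices, integer `weight` edge attribute).

#' Build the gene co-occurrence network
#'
#' Edge (g, h) carries weight equal to the number of abstracts whose gene
#' set contains both g and h. Genes never co-mentioned with another gene
#' remain as isolated vertices.
#'
#' @param x An annotated [corpus()].
#' @return An undirected weighted `igraph` graph.
#' @export
build_network <- function(x) {
  stopifnot(inherits(x, "lit_corpus"))
  gene_sets <- lapply(x$records, function(r) r$genes %||% character())
  nodes <- sort(unique(unlist(gene_sets)))
  all_keys <- unlist(lapply(gene_sets, function(g) {
    if (length(g) < 2L) return(character())
    p <- utils::combn(sort(g), 2L)
    paste(p[1, ], p[2, ], sep = "\r")
  }))
  if (length(all_keys)) {
    tab <- table(all_keys)
    parts <- strsplit(names(tab), "\r", fixed = TRUE)
    edges <- data.frame(
      from = vapply(parts, `[`, character(1), 1L),
      to = vapply(parts, `[`, character(1), 2L),
      weight = as.integer(tab),
      stringsAsFactors = FALSE
    )
  } else {
    edges <- data.frame(from = character(), to = character(), weight = integer())
  }
  igraph::graph_from_data_frame(edges,
    directed = FALSE,
    vertices = data.frame(name = nodes)
  )
}

#' Extract the giant component
#'
#' The connected component with the most nodes; ties go to the component
#' with more edges, then to the one containing the lexicographically
#' smallest vertex name.
#'
#' @param net An `igraph` graph.
#' @return The induced subgraph.
#' @export
giant_component <- function(net) {
  if (igraph::vcount(net) == 0L) stop("empty network", call. = FALSE)
  comp <- igraph::components(net)
  sizes <- comp$csize
  best <- which(sizes == max(sizes))
  if (length(best) > 1L) {
    n_edges <- vapply(best, function(b) {
      igraph::ecount(igraph::induced_subgraph(net, which(comp$membership == b)))
    }, numeric(1))
    best <- best[n_edges == max(n_edges)]
    if (length(best) > 1L) {
      first_name <- vapply(best, function(b) {
        min(igraph::V(net)$name[comp$membership == b])
      }, character(1))
      best <- best[order(first_name)[1]]
    }
  }
  igraph::induced_subgraph(net, which(comp$membership == best[1]))
}

#' Prune weak edges
#'
#' Drops every edge with weight strictly below `min_weight`, then drops
#' vertices left without any edge.
#'
#' @param net An `igraph` graph with a `weight` edge attribute.
#' @param min_weight Minimum surviving edge weight (default 10, the
#'   pipeline's noise cut for corpus-scale networks).
#' @return The pruned graph.
#' @export
prune_network <- function(net, min_weight = 10) {
  stopifnot(min_weight >= 1)
  if (igraph::ecount(net) > 0) {
    net <- igraph::delete_edges(
      net, which(igraph::E(net)$weight < min_weight)
    )
  }
  igraph::delete_vertices(net, which(igraph::degree(net) == 0))
}

#' Betweenness and closeness centralities
#'
#' Computed on the unweighted skeleton (each edge counts distance 1) and
#' normalized to `[0, 1]`: betweenness by `(n-1)(n-2)/2`, closeness as
#' harmonic centrality divided by `n - 1`, which stays well-defined on
#' disconnected graphs.
#'
#' @param net An `igraph` graph.
#' @return Data frame `gene`, `betweenness`, `closeness`, ordered by
#'   vertex name.
#' @export
network_centralities <- function(net) {
  n <- igraph::vcount(net)
  if (n == 0L) {
    return(data.frame(
      gene = character(), betweenness = numeric(), closeness = numeric()
    ))
  }
  if (n == 1L) {
    btw <- 0
    clo <- 0
  } else {
    btw <- igraph::betweenness(net, weights = NA, normalized = TRUE)
    clo <- igraph::harmonic_centrality(net, weights = NA) / (n - 1)
  }
  df <- data.frame(
    gene = igraph::V(net)$name,
    betweenness = unname(btw),
    closeness = unname(clo),
    stringsAsFactors = FALSE
  )
  df <- df[order(df$gene), , drop = FALSE]
  rownames(df) <- NULL
  df
}

#' Modularity communities
#'
#' Greedy multilevel modularity maximization (Louvain) on the weighted
#' graph, made deterministic by a fixed seed. Labels are 0-based and
#' contiguous, assigned in order of each community's first vertex.
#'
#' @param net An `igraph` graph.
#' @param seed Integer RNG seed.
#' @param resolution Modularity resolution parameter.
#' @return List with `membership` (data frame `gene`,
#'   `modularity_class`) and `modularity` (the partition's score).
#' @export
network_communities <- function(net, seed = 1L, resolution = 1.0) {
  n <- igraph::vcount(net)
  if (igraph::ecount(net) == 0L) {
    memb <- data.frame(
      gene = igraph::V(net)$name,
      modularity_class = seq_len(n) - 1L,
      stringsAsFactors = FALSE
    )
    return(list(membership = memb, modularity = 0))
  }
  cl <- with_seed(seed, igraph::cluster_louvain(net, resolution = resolution))
  raw <- igraph::membership(cl)
  relabel <- stats::setNames(seq_along(unique(raw)) - 1L, unique(raw))
  memb <- data.frame(
    gene = igraph::V(net)$name,
    modularity_class = unname(relabel[as.character(raw)]),
    stringsAsFactors = FALSE
  )
  list(
    membership = memb,
    modularity = igraph::modularity(net, raw, weights = igraph::E(net)$weight)
  )
}

stage_counts <- function(stage) {
  if (inherits(stage, "igraph")) {
    c(nodes = igraph::vcount(stage), edges = igraph::ecount(stage))
  } else {
    stopifnot(is.numeric(stage), length(stage) == 2L)
    c(nodes = stage[[1]], edges = stage[[2]])
  }
}

#' Summarize network reduction stages
#'
#' Node and edge counts for the full network, its giant component, and
#' the pruned giant component, with percentages relative to the full
#' network rounded to two decimals. Percentages are always recomputed
#' from the counts, never taken on trust.
#'
#' @param full,giant,pruned Each an `igraph` graph or a length-2 numeric
#'   `c(nodes, edges)`.
#' @return Data frame with rows `full`, `giant`, `pruned` and columns
#'   `nodes`, `node_pct`, `edges`, `edge_pct`.
#' @export
network_summary <- function(full, giant, pruned) {
  f <- stage_counts(full)
  g <- stage_counts(giant)
  p <- stage_counts(pruned)
  if (g["nodes"] > f["nodes"] || g["edges"] > f["edges"] ||
    p["nodes"] > g["nodes"] || p["edges"] > g["edges"]) {
    stop("inconsistent stages: counts must be non-increasing", call. = FALSE)
  }
  m <- rbind(full = f, giant = g, pruned = p)
  data.frame(
    stage = rownames(m),
    nodes = m[, "nodes"],
    node_pct = round2(100 * m[, "nodes"] / f[["nodes"]]),
    edges = m[, "edges"],
    edge_pct = round2(100 * m[, "edges"] / f[["edges"]]),
    row.names = NULL,
    stringsAsFactors = FALSE
  )
}

#' Export a network as a weighted edge list or GraphML
#'
#' @param net An `igraph` graph.
#' @param path Output path.
#' @export
write_edge_list <- function(net, path) {
  e <- igraph::as_data_frame(net, what = "edges")
  utils::write.table(e[, c("from", "to", "weight")], path,
    sep = "\t", quote = FALSE, row.names = FALSE, col.names = FALSE
  )
  invisible(path)
}

#' @rdname write_edge_list
#' @export
write_graphml <- function(net, path) {
  igraph::write_graph(net, path, format = "graphml")
  invisible(path)
}
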