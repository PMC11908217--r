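# Temperature-averaged hydrophobic contact graphs and closeness centrality.
#
# Shortest paths are unweighted hop counts: the centrality definition used,
# C_i = (n - 1) / sum_j d(i, j), is written in terms of path length with no
# frequency weighting; edge weight (the average contact frequency) is
# retained as an edge attribute for reporting only. On a disconnected graph
# the component-scaled generalization
#   C_i = (r_i - 1) / sum_{j reachable} d(i, j) * (r_i - 1) / (n - 1)
# is used (r_i = size of i's connected component), which reduces exactly to
# the connected-graph formula.

#' Build the temperature-averaged hydrophobic residue graph
#'
#' Nodes are the residues participating in any hydrophobic contact row of the
#' matrix; an edge joins two residues iff their mean contact frequency across
#' the full temperature ladder exceeds `threshold`, with the mean as edge
#' weight.
#'
#' @param mat a `ContactFrequencyMatrix`
#' @param threshold minimum mean frequency for an edge (default 0.75)
#' @param type interaction type to restrict to (default `"hydrophobic"`;
#'   `NULL` uses all rows)
#' @return an igraph undirected graph with vertex attribute `name` (residue
#'   key) and edge attribute `weight` (mean frequency)
#' @export
build_hydrophobic_graph <- function(mat, threshold = 0.75,
                                    type = "hydrophobic") {
  stopifnot(inherits(mat, "ContactFrequencyMatrix"))
  keys <- rownames(mat$freq)
  kd <- parse_contact_keys(keys)
  sel <- if (is.null(type)) rep(TRUE, length(keys)) else kd$type %in% type
  kd <- kd[sel, , drop = FALSE]
  M <- mat$freq[sel, , drop = FALSE]
  if (nrow(M) == 0) {
    message("no contacts of type '", type, "' in matrix; returning empty graph")
    return(igraph::make_empty_graph(directed = FALSE))
  }
  nodes <- sort(unique(c(kd$res_a, kd$res_b)))
  means <- rowMeans(M)
  keep <- means > threshold & kd$res_a != kd$res_b
  g <- igraph::graph_from_data_frame(
    data.frame(from = kd$res_a[keep], to = kd$res_b[keep],
               weight = means[keep], stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  igraph::simplify(g, edge.attr.comb = "max")
}

#' Closeness centrality of every residue
#'
#' For node i in a connected graph, `C_i = (n - 1) / sum_j d(i, j)` with
#' d(i, j) the shortest-path hop count; on disconnected graphs the
#' component-scaled generalization (see package docs) is used, so isolated
#' nodes score 0 and values stay in `[0, 1]`.
#'
#' @param graph an igraph undirected graph
#' @return a `CentralityProfile` data.frame with columns `key`, `cc`, and
#'   attribute `n` (node count)
#' @export
closeness_centrality <- function(graph) {
  n <- igraph::vcount(graph)
  keys <- if (n > 0) igraph::V(graph)$name else character(0)
  if (n <= 1) {
    out <- data.frame(key = keys, cc = numeric(n), stringsAsFactors = FALSE)
  } else {
    D <- igraph::distances(graph, weights = NA)
    cc <- vapply(seq_len(n), function(i) {
      d <- D[i, -i]
      reach <- is.finite(d)
      r <- sum(reach) + 1L
      if (r == 1L) return(0)
      ((r - 1) / sum(d[reach])) * ((r - 1) / (n - 1))
    }, numeric(1))
    out <- data.frame(key = keys, cc = cc, stringsAsFactors = FALSE)
  }
  attr(out, "n") <- n
  class(out) <- c("CentralityProfile", "data.frame")
  out
}

#' Extract the top-centrality subnetwork
#'
#' Keeps the top `ceiling(fraction * n)` nodes by closeness centrality (ties
#' broken by residue order) plus all edges among them.
#'
#' @param graph an igraph undirected graph
#' @param profile its `CentralityProfile` (recomputed when `NULL`)
#' @param fraction fraction of nodes to retain, in (0, 1]
#' @return the induced igraph subgraph
#' @export
top_cc_subnetwork <- function(graph, profile = NULL, fraction = 0.20) {
  stopifnot(fraction > 0, fraction <= 1)
  n <- igraph::vcount(graph)
  if (n == 0) return(graph)
  if (is.null(profile)) profile <- closeness_centrality(graph)
  keep_n <- ceiling(fraction * n)
  ord <- order(-profile$cc, profile$key)
  keep <- profile$key[ord[seq_len(keep_n)]]
  igraph::induced_subgraph(graph, which(igraph::V(graph)$name %in% keep))
}

#' Write a residue graph and centrality profile to disk
#'
#' @param graph an igraph graph
#' @param profile a `CentralityProfile`
#' @param edges_path CSV edge list (resA, resB, weight)
#' @param graphml_path GraphML output
#' @param cc_path CSV of residue, cc
#' @return invisibly `NULL`
#' @export
write_network <- function(graph, profile = NULL, edges_path = NULL,
                          graphml_path = NULL, cc_path = NULL) {
  if (!is.null(edges_path)) {
    e <- igraph::as_data_frame(graph, what = "edges")
    names(e)[1:2] <- c("resA", "resB")
    write.csv(e, edges_path, row.names = FALSE)
  }
  if (!is.null(graphml_path)) {
    igraph::write_graph(graph, graphml_path, format = "graphml")
  }
  if (!is.null(cc_path) && !is.null(profile)) {
    write.csv(data.frame(residue = profile$key, cc = profile$cc),
              cc_path, row.names = FALSE)
  }
  invisible(NULL)
}
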