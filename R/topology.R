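#' Topological summary of a network
#'
#' Computes the per-network topological eigenvalues used to characterise
#' co-occurrence networks: node count, edge count, average degree `2E/N`,
#' graph density `2E/(N(N-1))`, and the fraction of edges whose correlation
#' is negative. `format()`/`print()` round average degree and density to 3
#' decimals and report the negative fraction as a percentage with 2 decimals.
#'
#' @param net `conet`, or a plain undirected `igraph` graph (negative
#'   fraction then requires a `sign` edge attribute, else 0).
#' @return object of class `topology_summary`: one-row data.frame with
#'   columns `label`, `n_nodes`, `n_edges`, `average_degree`, `density`,
#'   `negative_fraction` (unrounded values).
#' @export
topology_summary <- function(net) {
  label <- NA_character_
  if (inherits(net, "conet")) {
    label <- net$label %||% NA_character_
    g <- net$graph
  } else if (inherits(net, "igraph")) {
    g <- net
  } else stopf("`net` must be a conet or igraph object")
  if (igraph::is_directed(g) || igraph::any_multiple(g) ||
      any(igraph::which_loop(g)))
    stopf("network must be undirected and simple")
  n <- igraph::gorder(g)
  if (n < 2L) stopf("density undefined for fewer than 2 nodes")
  e <- igraph::gsize(g)
  neg <- 0
  if (e && "sign" %in% igraph::edge_attr_names(g))
    neg <- mean(igraph::E(g)$sign == "negative")
  out <- data.frame(label = label, n_nodes = n, n_edges = e,
                    average_degree = 2 * e / n,
                    density = 2 * e / (n * (n - 1)),
                    negative_fraction = neg,
                    stringsAsFactors = FALSE)
  class(out) <- c("topology_summary", "data.frame")
  out
}

#' @export
summary.conet <- function(object, ...) topology_summary(object)

#' @export
format.topology_summary <- function(x, ...) {
  data.frame(label = x$label, n_nodes = x$n_nodes, n_edges = x$n_edges,
             average_degree = sprintf("%.3f", x$average_degree),
             density = sprintf("%.3f", x$density),
             negative_pct = sprintf("%.2f%%", 100 * x$negative_fraction),
             stringsAsFactors = FALSE)
}

#' @export
print.topology_summary <- function(x, ...) {
  print.data.frame(format(x), row.names = FALSE)
  invisible(x)
}

#' Betweenness centrality of network nodes
#'
#' Unnormalised shortest-path betweenness on the unweighted graph (endpoints
#' of a path do not count toward its intermediaries). Used to size nodes in
#' network figures.
#'
#' @param net `conet` or undirected `igraph` graph.
#' @return named numeric vector over nodes.
#' @export
node_betweenness <- function(net) {
  g <- if (inherits(net, "conet")) net$graph else net
  igraph::betweenness(g, directed = FALSE, weights = NA)
}

#' Deterministic simple graph with a given number of nodes and edges
#'
#' Takes the first `n_edges` pairs of the lexicographic upper triangle over
#' `n_nodes` labelled nodes. Useful for checking topology identities at a
#' prescribed (N, E).
#'
#' @param n_nodes,n_edges counts; `n_edges` at most `choose(n_nodes, 2)`.
#' @return undirected `igraph` graph.
#' @export
make_graph_nm <- function(n_nodes, n_edges) {
  if (n_edges > choose(n_nodes, 2))
    stopf("n_edges exceeds the simple-graph maximum")
  pairs <- utils::combn(n_nodes, 2L)[, seq_len(n_edges), drop = FALSE]
  igraph::add_edges(igraph::make_empty_graph(n_nodes, directed = FALSE),
                    as.vector(pairs))
}
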