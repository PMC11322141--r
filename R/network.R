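#' Build a co-occurrence network from a correlation result
#'
#' An (undirected, simple) edge is drawn between variables i and j exactly
#' when `|rho(i,j)| > rho_threshold` and the FDR-adjusted p-value is below
#' `alpha` (the threshold on rho is strict, so a correlation of exactly the
#' threshold is excluded). Edge sign is the sign of rho. Zero-variance
#' variables never form edges. Isolated nodes are retained in the node set by
#' default; node lineage attributes are attached from `taxonomy`.
#'
#' @param corr `correlation_result` from [spearman_all_pairs()].
#' @param taxonomy optional named character vector of lineage strings.
#' @param rho_threshold correlation magnitude threshold in (0, 1\]; default 0.6.
#' @param alpha significance level in (0, 1); default 0.01.
#' @param use_adjusted compare `alpha` against BH-adjusted p-values (default
#'   TRUE) or raw p-values.
#' @param keep_isolated retain nodes without edges (default TRUE).
#' @param node_class node class attribute, recycled over nodes ("otu" or
#'   "nutrient").
#' @return object of class `conet` (see [cooccurrence_network()]).
#' @export
build_network <- function(corr, taxonomy = NULL, rho_threshold = 0.6,
                          alpha = 0.01, use_adjusted = TRUE,
                          keep_isolated = TRUE, node_class = "otu") {
  stopifnot(inherits(corr, "correlation_result"))
  if (!is.numeric(rho_threshold) || rho_threshold <= 0 || rho_threshold > 1)
    stopf("`rho_threshold` must lie in (0, 1]")
  if (!is.numeric(alpha) || alpha <= 0 || alpha >= 1)
    stopf("`alpha` must lie in (0, 1)")
  ids <- corr$variable_ids
  pm <- if (use_adjusted) corr$p_adj else corr$p_raw
  ut <- which(upper.tri(corr$rho), arr.ind = TRUE)
  ok <- abs(corr$rho[ut]) > rho_threshold & pm[ut] < alpha &
    !(corr$constant[ut[, 1L]] | corr$constant[ut[, 2L]])
  sel <- ut[ok, , drop = FALSE]
  edges <- data.frame(
    node_a = ids[sel[, 1L]], node_b = ids[sel[, 2L]],
    rho = corr$rho[sel], p_raw = corr$p_raw[sel], p_adj = corr$p_adj[sel],
    sign = ifelse(corr$rho[sel] > 0, "positive", "negative"),
    stringsAsFactors = FALSE)

  nodes <- data.frame(name = ids, stringsAsFactors = FALSE)
  nodes$class <- rep_len(node_class, nrow(nodes))
  nodes$lineage <- if (is.null(taxonomy)) NA_character_
                   else unname(taxonomy[ids])
  if (!keep_isolated) {
    used <- unique(c(edges$node_a, edges$node_b))
    nodes <- nodes[nodes$name %in% used, , drop = FALSE]
  }
  g <- igraph::graph_from_data_frame(edges, directed = FALSE,
                                     vertices = nodes)
  new_conet(g, rho_threshold = rho_threshold, alpha = alpha,
            use_adjusted = use_adjusted, n_samples = corr$n_samples)
}

new_conet <- function(graph, rho_threshold, alpha, use_adjusted, n_samples,
                      label = NULL) {
  igraph::V(graph)$betweenness <-
    igraph::betweenness(graph, directed = FALSE, weights = NA)
  structure(list(graph = graph, rho_threshold = rho_threshold,
                 alpha = alpha, use_adjusted = use_adjusted,
                 n_samples = n_samples, label = label),
            class = "conet")
}

#' Fit a microbial co-occurrence network from an OTU table
#'
#' The central estimator of the package: preprocesses an OTU count table
#' (optional low-abundance filter), computes all-pairs Spearman correlations
#' on relative abundances, applies Benjamini-Hochberg FDR correction over all
#' distinct pairs, and keeps as edges the pairs with `|rho| >` the threshold
#' and adjusted p below `alpha`. If a nutrient series is supplied, the three
#' nutrient concentrations (TS, TN, TP) enter as extra variables and the
#' result is pruned to the nutrient-associated subgraph (see
#' [nutrient_network()]).
#'
#' @param x `otu_table`.
#' @param rho_threshold,alpha,use_adjusted,keep_isolated see
#'   [build_network()].
#' @param filter_threshold mean relative-abundance threshold applied before
#'   correlation (default `1e-4`, i.e. 0.01\%); `NULL` to skip filtering.
#' @param nutrients optional `nutrient_series` joined to samples by
#'   (day, port).
#' @param label optional network label (e.g. the day or stage it covers).
#' @return object of class `conet`: a list with the `igraph` graph (node
#'   attributes `class`, `lineage`, `betweenness`; edge attributes `rho`,
#'   `p_raw`, `p_adj`, `sign`), the construction thresholds, and the sample
#'   size. Methods: `print`, `summary` (= [topology_summary()]), `plot`.
#' @export
cooccurrence_network <- function(x, rho_threshold = 0.6, alpha = 0.01,
                                 use_adjusted = TRUE, keep_isolated = TRUE,
                                 filter_threshold = 1e-4, nutrients = NULL,
                                 label = NULL) {
  stopifnot(inherits(x, "otu_table"))
  if (!is.null(filter_threshold))
    x <- filter_low_abundance(x, filter_threshold)
  if (!is.null(nutrients))
    return(nutrient_network(x, nutrients, rho_threshold = rho_threshold,
                            alpha = alpha, use_adjusted = use_adjusted,
                            filter_threshold = NULL, label = label))
  corr <- spearman_all_pairs(relative_abundance(x))
  net <- build_network(corr, taxonomy = x$taxonomy,
                       rho_threshold = rho_threshold, alpha = alpha,
                       use_adjusted = use_adjusted,
                       keep_isolated = keep_isolated)
  net$label <- label
  net
}

#' Nutrient-OTU bipartite co-occurrence network
#'
#' Adds the three nutrient concentrations (TS, TN, TP) as variables alongside
#' the OTU relative abundances, builds the co-occurrence network with the
#' same Spearman/FDR/threshold rule as [cooccurrence_network()], and then
#' removes every OTU node without a direct edge to a nutrient node. OTU-OTU
#' edges among the retained OTUs are kept, as are the nutrient nodes
#' themselves.
#'
#' @param x `otu_table`; every sample must have a matching (day, port)
#'   nutrient record.
#' @param nutrients `nutrient_series` (or data.frame with columns `day`,
#'   `port`, `TS`, `TN`, `TP`).
#' @param rho_threshold,alpha,use_adjusted see [build_network()].
#' @param filter_threshold optional abundance filter (as in
#'   [cooccurrence_network()]); default `1e-4`.
#' @param label optional network label.
#' @return `conet` whose nodes carry `class` "otu" or "nutrient".
#' @export
nutrient_network <- function(x, nutrients, rho_threshold = 0.6, alpha = 0.01,
                             use_adjusted = TRUE, filter_threshold = 1e-4,
                             label = NULL) {
  stopifnot(inherits(x, "otu_table"))
  nutrients <- as.data.frame(nutrients)
  if (!is.null(filter_threshold))
    x <- filter_low_abundance(x, filter_threshold)
  key_n <- paste(nutrients$day, nutrients$port)
  key_s <- paste(x$metadata$day, x$metadata$port)
  hit <- match(key_s, key_n)
  if (anyNA(hit)) {
    missing <- unique(key_s[is.na(hit)])
    stopf("no nutrient record for (day, port): %s",
          paste(missing, collapse = "; "))
  }
  nut_mat <- t(as.matrix(nutrients[hit, c("TS", "TN", "TP")]))
  colnames(nut_mat) <- colnames(x$counts)
  m <- rbind(relative_abundance(x), nut_mat)
  corr <- spearman_all_pairs(m)
  cls <- c(rep("otu", n_otus(x)), rep("nutrient", 3L))
  names(cls) <- rownames(m)
  tax <- c(x$taxonomy %||% stats::setNames(rep(NA_character_, n_otus(x)),
                                           rownames(x$counts)),
           stats::setNames(c("total sugars", "total nitrogen",
                             "total phosphorus"), c("TS", "TN", "TP")))
  net <- build_network(corr, taxonomy = tax, rho_threshold = rho_threshold,
                       alpha = alpha, use_adjusted = use_adjusted,
                       keep_isolated = TRUE, node_class = cls[rownames(m)])
  g <- net$graph
  nut_idx <- which(igraph::V(g)$class == "nutrient")
  keep <- unique(c(nut_idx,
                   unlist(igraph::adjacent_vertices(g, nut_idx))))
  g <- igraph::induced_subgraph(g, sort(keep))
  net <- new_conet(g, rho_threshold, alpha, use_adjusted, corr$n_samples,
                   label = label)
  net
}

#' @export
print.conet <- function(x, ...) {
  g <- x$graph
  neg <- if (igraph::gsize(g)) mean(igraph::E(g)$sign == "negative") else 0
  cat(sprintf("Co-occurrence network%s: %d nodes, %d edges (%.1f%% negative)\n",
              if (is.null(x$label)) "" else paste0(" [", x$label, "]"),
              igraph::gorder(g), igraph::gsize(g), 100 * neg))
  cat(sprintf("  thresholds: |rho| > %g, %s p < %g; n = %d samples\n",
              x$rho_threshold, if (x$use_adjusted) "FDR-adjusted" else "raw",
              x$alpha, x$n_samples))
  invisible(x)
}

#' @export
plot.conet <- function(x, vertex_scale = 3, ...) {
  g <- x$graph
  ec <- if (igraph::gsize(g))
    ifelse(igraph::E(g)$sign == "negative", "red", "grey50") else NULL
  vc <- ifelse(igraph::V(g)$class == "nutrient", "tomato", "skyblue")
  bt <- igraph::V(g)$betweenness
  sz <- 3 + vertex_scale * sqrt(bt / max(bt, 1))
  igraph::plot.igraph(g, edge.color = ec, vertex.color = vc,
                      vertex.size = sz, vertex.label = NA, ...)
  invisible(x)
}

#' Edge list of a network as a data.frame
#'
#' @param net `conet`.
#' @return data.frame with columns `node_a`, `node_b`, `rho`, `p_raw`,
#'   `p_adj`, `sign`.
#' @export
edge_list <- function(net) {
  stopifnot(inherits(net, "conet"))
  g <- net$graph
  el <- igraph::as_edgelist(g)
  if (!nrow(el))
    return(data.frame(node_a = character(), node_b = character(),
                      rho = numeric(), p_raw = numeric(), p_adj = numeric(),
                      sign = character(), stringsAsFactors = FALSE))
  data.frame(node_a = el[, 1L], node_b = el[, 2L],
             rho = igraph::E(g)$rho, p_raw = igraph::E(g)$p_raw,
             p_adj = igraph::E(g)$p_adj, sign = igraph::E(g)$sign,
             stringsAsFactors = FALSE)
}

#' Node table of a network as a data.frame
#'
#' @param net `conet`.
#' @return data.frame with columns `node`, `class`, `lineage`, `degree`,
#'   `betweenness`.
#' @export
node_table <- function(net) {
  stopifnot(inherits(net, "conet"))
  g <- net$graph
  data.frame(node = igraph::V(g)$name, class = igraph::V(g)$class,
             lineage = igraph::V(g)$lineage, degree = igraph::degree(g),
             betweenness = igraph::V(g)$betweenness,
             row.names = NULL, stringsAsFactors = FALSE)
}

#' Write network outputs (edge list, node table, GraphML)
#'
#' @param net `conet`.
#' @param edge_path,node_path,graphml_path output paths (any may be `NULL`
#'   to skip).
#' @return invisibly, the paths written.
#' @export
write_network <- function(net, edge_path = NULL, node_path = NULL,
                          graphml_path = NULL) {
  stopifnot(inherits(net, "conet"))
  written <- character()
  if (!is.null(edge_path)) {
    utils::write.table(edge_list(net), edge_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, edge_path)
  }
  if (!is.null(node_path)) {
    utils::write.table(node_table(net), node_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
    written <- c(written, node_path)
  }
  if (!is.null(graphml_path)) {
    g <- net$graph
    igraph::V(g)$lineage[is.na(igraph::V(g)$lineage)] <- ""
    igraph::write_graph(g, graphml_path, format = "graphml")
    written <- c(written, graphml_path)
  }
  invisible(written)
}

#' Precision and recall of a network against planted edges
#'
#' Compares the fitted edge set (as unordered OTU pairs) with a planted
#' ground-truth edge list. Nutrient nodes and their edges are ignored.
#'
#' @param net `conet`.
#' @param truth `ground_truth` from [simulate_counts()], or a data.frame with
#'   columns `otu_a`, `otu_b`.
#' @param stage which planted stage to score against (see [planted_edges()]).
#' @return list with `precision`, `recall`, `tp`, `fp`, `fn`.
#' @export
edge_recovery <- function(net, truth, stage = "any") {
  el <- edge_list(net)
  cls <- node_table(net)
  nut <- cls$node[cls$class == "nutrient"]
  el <- el[!(el$node_a %in% nut | el$node_b %in% nut), , drop = FALSE]
  planted <- if (inherits(truth, "ground_truth")) planted_edges(truth, stage)
             else truth
  key <- function(a, b) paste(pmin(a, b), pmax(a, b))
  got <- key(el$node_a, el$node_b)
  want <- key(planted$otu_a, planted$otu_b)
  tp <- sum(got %in% want)
  list(precision = if (length(got)) tp / length(got) else NA_real_,
       recall = if (length(want)) tp / length(want) else NA_real_,
       tp = tp, fp = length(got) - tp, fn = length(want) - tp)
}
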