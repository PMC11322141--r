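#' Network robustness under random node removal
#'
#' Monte-Carlo assessment of structural stability: per replicate,
#' `floor(fraction * N)` nodes are removed uniformly at random without
#' replacement and the proportion of remaining nodes is recorded. By default
#' a node "remains" if it keeps at least one edge in the induced subgraph,
#' and the proportion is taken over the ORIGINAL node count N; higher values
#' mean a more stable network.
#'
#' @param net `conet` or undirected `igraph` graph.
#' @param fraction removal fraction, strictly between 0 and 1.
#' @param n_reps Monte-Carlo replicates (default 1000).
#' @param seed RNG seed (required; results are deterministic given it).
#' @param denominator `"original"` (default: proportion of all N nodes) or
#'   `"survivors"` (proportion of the N - floor(fraction*N) surviving nodes).
#' @param measure `"non_isolated"` (default: surviving nodes with degree >=
#'   1) or `"lcc"` (size of the largest connected component of the induced
#'   subgraph).
#' @param return_sets also return the removed node sets (default FALSE).
#' @return object of class `robustness_point`: list with `fraction`,
#'   `n_removed`, `mean`, `sd`, `replicates` (numeric vector of length
#'   `n_reps`), and optionally `removed` (list of character vectors).
#' @export
robustness_random_removal <- function(net, fraction, n_reps = 1000, seed,
                                      denominator = c("original", "survivors"),
                                      measure = c("non_isolated", "lcc"),
                                      return_sets = FALSE) {
  g <- if (inherits(net, "conet")) net$graph else net
  stopifnot(inherits(g, "igraph"))
  denominator <- match.arg(denominator)
  measure <- match.arg(measure)
  if (!is.numeric(fraction) || fraction <= 0 || fraction >= 1)
    stopf("`fraction` must lie strictly in (0, 1)")
  if (!is_count(n_reps)) stopf("`n_reps` must be a positive integer")
  if (missing(seed)) stopf("`seed` is required")
  n <- igraph::gorder(g)
  n_rm <- floor(fraction * n)
  adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
  names <- igraph::V(g)$name %||% as.character(seq_len(n))
  denom <- if (denominator == "original") n else max(n - n_rm, 1L)

  sets <- with_seed(seed, lapply(seq_len(n_reps),
                                 function(i) sample.int(n, n_rm)))
  reps <- vapply(sets, function(rm) {
    keep <- setdiff(seq_len(n), rm)
    if (!length(keep)) return(0)
    sub <- adj[keep, keep, drop = FALSE]
    if (measure == "non_isolated") {
      sum(rowSums(sub) > 0) / denom
    } else {
      sg <- igraph::graph_from_adjacency_matrix(sub, mode = "undirected")
      max(igraph::components(sg)$csize) / denom
    }
  }, numeric(1))

  out <- list(fraction = fraction, n_removed = n_rm,
              mean = mean(reps), sd = stats::sd(reps), n_reps = n_reps,
              replicates = reps)
  if (return_sets) out$removed <- lapply(sets, function(rm) names[rm])
  class(out) <- "robustness_point"
  out
}

#' @export
print.robustness_point <- function(x, ...) {
  cat(sprintf(
    "Robustness at removal fraction %.2f: mean remaining %.4f (sd %.4f, %d reps)\n",
    x$fraction, x$mean, x$sd, x$n_reps))
  invisible(x)
}

#' Robustness curve over a grid of removal fractions
#'
#' Applies [robustness_random_removal()] at every fraction of the grid, with
#' an independent seeded substream per fraction.
#'
#' @param net `conet` or undirected `igraph` graph.
#' @param fractions strictly increasing grid in (0, 1); default
#'   `seq(0.05, 0.95, by = 0.05)`.
#' @param n_reps,seed,denominator,measure as in
#'   [robustness_random_removal()].
#' @return object of class `robustness_curve`: data.frame with columns
#'   `fraction`, `mean`, `sd`, `n_reps`; attribute `points` holds the
#'   per-fraction `robustness_point` objects.
#' @export
robustness_curve <- function(net, fractions = seq(0.05, 0.95, by = 0.05),
                             n_reps = 1000, seed,
                             denominator = "original",
                             measure = "non_isolated") {
  if (missing(seed)) stopf("`seed` is required")
  if (any(diff(fractions) <= 0) || any(fractions <= 0 | fractions >= 1))
    stopf("`fractions` must be strictly increasing within (0, 1)")
  pts <- lapply(seq_along(fractions), function(i)
    robustness_random_removal(net, fractions[i], n_reps = n_reps,
                              seed = child_seed(seed, i),
                              denominator = denominator, measure = measure))
  out <- data.frame(fraction = fractions,
                    mean = vapply(pts, `[[`, numeric(1), "mean"),
                    sd = vapply(pts, `[[`, numeric(1), "sd"),
                    n_reps = n_reps)
  attr(out, "points") <- pts
  class(out) <- c("robustness_curve", "data.frame")
  out
}

#' @export
plot.robustness_curve <- function(x, ...) {
  graphics::plot(x$fraction, x$mean, type = "b", pch = 16,
                 xlab = "fraction of nodes removed",
                 ylab = "proportion of remaining nodes", ylim = c(0, 1), ...)
  graphics::arrows(x$fraction, pmax(x$mean - x$sd, 0),
                   x$fraction, pmin(x$mean + x$sd, 1),
                   angle = 90, code = 3, length = 0.03)
  invisible(x)
}
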