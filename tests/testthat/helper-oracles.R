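# Independent brute-force oracles. These deliberately avoid the package's
# code paths (and rank()/cor()/p.adjust()) so that agreement is evidence,
# not tautology.

# mid-ranks by counting: rank = (#smaller) + (#equal + 1)/2
oracle_ranks <- function(v) {
  vapply(v, function(x) sum(v < x) + (sum(v == x) + 1) / 2, numeric(1))
}

# Pearson correlation from the definition (sum formulas)
oracle_pearson <- function(x, y) {
  n <- length(x)
  sx <- x - sum(x) / n
  sy <- y - sum(y) / n
  sum(sx * sy) / sqrt(sum(sx^2) * sum(sy^2))
}

oracle_spearman <- function(x, y) {
  oracle_pearson(oracle_ranks(x), oracle_ranks(y))
}

# two-sided p from the t-approximation to the null of rho
oracle_spearman_p <- function(rho, n) {
  if (abs(rho) >= 1) return(0)
  t <- rho * sqrt((n - 2) / (1 - rho^2))
  2 * stats::pt(abs(t), df = n - 2, lower.tail = FALSE)
}

# Benjamini-Hochberg step-up by explicit sorting and cumulative minimum
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  scaled <- p[ord] * m / seq_len(m)
  adj <- rev(cummin(rev(scaled)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[ord] <- adj
  out
}

# full edge-calling oracle: matrix (variables x samples) -> sorted edge keys
oracle_edge_set <- function(m, rho_threshold = 0.6, alpha = 0.01) {
  v <- nrow(m)
  n <- ncol(m)
  pairs <- utils::combn(v, 2L)
  rho <- p <- numeric(ncol(pairs))
  for (k in seq_len(ncol(pairs))) {
    i <- pairs[1L, k]; j <- pairs[2L, k]
    const <- length(unique(m[i, ])) == 1L || length(unique(m[j, ])) == 1L
    rho[k] <- if (const) 0 else oracle_spearman(m[i, ], m[j, ])
    p[k] <- if (const) 1 else oracle_spearman_p(rho[k], n)
  }
  padj <- oracle_bh(p)
  hit <- abs(rho) > rho_threshold & padj < alpha
  ids <- rownames(m) %||% paste0("V", seq_len(v))
  a <- ids[pairs[1L, hit]]
  b <- ids[pairs[2L, hit]]
  sort(paste(pmin(a, b), pmax(a, b)))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

# exhaustive mean remaining-node proportion after removing k of n nodes
oracle_robustness_mean <- function(adj, k) {
  n <- nrow(adj)
  sets <- utils::combn(n, k)
  vals <- apply(sets, 2L, function(rm) {
    keep <- setdiff(seq_len(n), rm)
    sub <- adj[keep, keep, drop = FALSE]
    sum(rowSums(sub) > 0) / n
  })
  mean(vals)
}

# conet edge set as sorted unordered keys, for oracle comparison
net_edge_keys <- function(net) {
  el <- edge_list(net)
  sort(paste(pmin(el$node_a, el$node_b), pmax(el$node_a, el$node_b)))
}

# small scaled-down scenario used across tests (block params fit n_otus)
tiny_scenario <- function(n_otus = 30, days = 1:12, n_ports = 3,
                          depth = 2000, ...) {
  sim_scenario(n_otus = n_otus, days = days, n_ports = n_ports,
               sequencing_depth = depth, n_blocks_high = 2, n_blocks_low = 2,
               block_size = 3, nutrient_blocks = FALSE, ...)
}
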