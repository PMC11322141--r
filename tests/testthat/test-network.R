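fake_corr <- function(rho, p_adj, ids = LETTERS[seq_len(nrow(rho))]) {
  dimnames(rho) <- dimnames(p_adj) <- list(ids, ids)
  structure(list(rho = rho, p_raw = p_adj, p_adj = p_adj, n_samples = 50,
                 variable_ids = ids, constant = rep(FALSE, length(ids))),
            class = "correlation_result")
}

sym <- function(v, n) {
  m <- matrix(0, n, n)
  m[upper.tri(m)] <- v
  m + t(m)
}

test_that("edge inclusion uses strict |rho| > threshold and p_adj < alpha", {
  # pairs: (A,B) rho exactly 0.6 -> excluded; (A,C) -0.7 significant ->
  # included negative; (B,C) 0.9 but p_adj too large -> excluded
  rho <- sym(c(0.6, -0.7, 0.9), 3); diag(rho) <- 1
  padj <- sym(c(1e-4, 0.005, 0.02), 3)
  net <- build_network(fake_corr(rho, padj))
  el <- edge_list(net)
  expect_equal(nrow(el), 1L)
  expect_equal(sort(c(el$node_a, el$node_b)), c("A", "C"))
  expect_equal(el$sign, "negative")
  expect_equal(igraph::gorder(net$graph), 3L)  # isolated nodes retained

  net2 <- build_network(fake_corr(rho, padj), keep_isolated = FALSE)
  expect_equal(igraph::gorder(net2$graph), 2L)
})

test_that("the worked three-variable case yields two edges, one negative", {
  rho <- sym(c(0.9, -0.7, 0.9), 3); diag(rho) <- 1
  padj <- sym(c(0.001, 0.005, 0.02), 3)
  net <- build_network(fake_corr(rho, padj))
  el <- edge_list(net)
  expect_equal(nrow(el), 2L)
  expect_equal(sum(el$sign == "negative"), 1L)
})

test_that("sub-threshold correlations produce an empty edge set", {
  rho <- sym(c(0.5, -0.59, 0.3), 3); diag(rho) <- 1
  padj <- sym(rep(1e-6, 3), 3)
  expect_equal(nrow(edge_list(build_network(fake_corr(rho, padj)))), 0L)
})

test_that("threshold and alpha are validated", {
  rho <- diag(2); padj <- matrix(0, 2, 2)
  expect_error(build_network(fake_corr(rho, padj), rho_threshold = 0), "0, 1")
  expect_error(build_network(fake_corr(rho, padj), alpha = 1), "0, 1")
})

test_that("edge calling matches the brute-force oracle on random instances", {
  set.seed(2024)
  for (i in 1:25) {
    v <- sample(4:8, 1); n <- sample(8:12, 1)
    m <- matrix(rnorm(v * n), nrow = v,
                dimnames = list(sprintf("V%02d", 1:v), NULL))
    # plant a couple of near-duplicate rows so edges actually occur
    for (k in seq_len(sample(0:2, 1))) {
      ij <- sample(v, 2)
      m[ij[2], ] <- m[ij[1], ] * sample(c(1, -1), 1) + rnorm(n, sd = 0.05)
    }
    if (i %% 5 == 0) m[sample(v, 1), ] <- 3  # occasional constant variable
    net <- build_network(spearman_all_pairs(m))
    expect_identical(net_edge_keys(net), oracle_edge_set(m))
  }
})

test_that("the edge set ignores sample and OTU ordering", {
  set.seed(55)
  sc <- tiny_scenario()
  sim <- simulate_counts(sc, seed = 2)
  tab <- sim$table
  net <- cooccurrence_network(tab, filter_threshold = NULL)
  perm_o <- sample(nrow(tab$counts)); perm_s <- sample(ncol(tab$counts))
  tab2 <- otu_table(tab$counts[perm_o, perm_s],
                    tab$metadata[perm_s, ], tab$taxonomy[perm_o])
  net2 <- cooccurrence_network(tab2, filter_threshold = NULL)
  expect_identical(net_edge_keys(net), net_edge_keys(net2))
})

test_that("network negative-edge fraction matches direct edge accounting", {
  sim <- simulate_counts(tiny_scenario(), seed = 6)
  net <- cooccurrence_network(sim$table)
  el <- edge_list(net)
  ts <- topology_summary(net)
  expect_equal(ts$negative_fraction,
               if (nrow(el)) sum(el$rho < 0) / nrow(el) else 0)
  expect_true(all((el$rho < 0) == (el$sign == "negative")))
})

test_that("nutrient joins fail loudly when a sample lacks a record", {
  sim <- simulate_community(tiny_scenario(), seed = 3)
  nut <- sim$nutrients
  nut <- nut[!(nut$day == 2 & nut$port == "SP3"), ]
  expect_error(nutrient_network(sim$table, nut), "2 SP3")
})

test_that("an OTU monotone in TS keeps a positive TS edge; unrelated OTUs are pruned", {
  set.seed(10)
  n <- 16
  # the monotone OTU stays a tiny share of the library so the compositional
  # closure does not couple the unrelated OTUs to TS
  counts <- rbind(
    OTUts = 50 * (1:n),                       # monotone in TS
    OTUa = rpois(n, 5e4), OTUb = rpois(n, 5e4), OTUc = rpois(n, 5e4))
  colnames(counts) <- sprintf("S%d", 1:n)
  meta <- data.frame(sample = colnames(counts), day = 1:n, port = "SP2",
                     stage = "high", stringsAsFactors = FALSE)
  tab <- otu_table(counts, meta)
  nut <- data.frame(day = 1:n, port = "SP2", TS = (1:n) + rnorm(n, sd = 0.01),
                    TN = rnorm(n, 50), TP = rnorm(n, 20))
  net <- nutrient_network(tab, nut, filter_threshold = NULL)
  nodes <- node_table(net)
  expect_true("OTUts" %in% nodes$node)
  el <- edge_list(net)
  ts_edge <- el[(el$node_a == "OTUts" & el$node_b == "TS") |
                (el$node_b == "OTUts" & el$node_a == "TS"), ]
  expect_equal(nrow(ts_edge), 1L)
  expect_equal(ts_edge$sign, "positive")
  # OTUs uncorrelated with any nutrient do not survive the pruning
  expect_setequal(nodes$node, c("OTUts", "TS", "TN", "TP"))
})

test_that("a TN-driven planted block connects to the TN node", {
  for (seed in 1:3) {
    sc <- sim_scenario(n_otus = 20, days = 1:30, n_ports = 4,
                       stage_boundary_day = 16,
                       block_spec = data.frame(size = 4, rho = 0.9, sign = 1,
                                               stage = "both", driver = "TN"),
                       sequencing_depth = 5000)
    sim <- simulate_community(sc, seed = seed)
    net <- nutrient_network(sim$table, sim$nutrients, filter_threshold = NULL)
    members <- unique(c(sim$truth$edges$otu_a, sim$truth$edges$otu_b))
    el <- edge_list(net)
    tn_partners <- c(el$node_b[el$node_a == "TN"], el$node_a[el$node_b == "TN"])
    expect_true(all(members %in% tn_partners))
  }
})

test_that("network files are written and GraphML re-imports", {
  sim <- simulate_counts(tiny_scenario(), seed = 8)
  net <- cooccurrence_network(sim$table)
  ep <- tempfile(fileext = ".tsv"); np <- tempfile(fileext = ".tsv")
  gp <- tempfile(fileext = ".graphml")
  write_network(net, ep, np, gp)
  expect_true(all(file.exists(ep, np, gp)))
  g <- igraph::read_graph(gp, format = "graphml")
  expect_equal(igraph::gorder(g), igraph::gorder(net$graph))
  expect_equal(igraph::gsize(g), igraph::gsize(net$graph))
})
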