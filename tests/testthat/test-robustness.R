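test_that("K10 at half removal keeps exactly half the nodes, every replicate", {
  pt <- robustness_random_removal(igraph::make_full_graph(10), 0.5,
                                  n_reps = 50, seed = 3)
  expect_true(all(pt$replicates == 0.5))
  expect_equal(pt$mean, 0.5)
  expect_equal(pt$n_removed, 5L)
})

test_that("a star collapses to zero whenever the hub is removed", {
  star <- igraph::make_star(10, mode = "undirected", center = 1)
  igraph::V(star)$name <- c("hub", paste0("leaf", 1:9))
  pt <- robustness_random_removal(star, 0.5, n_reps = 200, seed = 9,
                                  return_sets = TRUE)
  hub_gone <- vapply(pt$removed, function(s) "hub" %in% s, logical(1))
  expect_true(any(hub_gone))
  expect_true(all(pt$replicates[hub_gone] == 0))
  # hub kept: 5 survivors, all leaves attached to the hub
  expect_true(all(pt$replicates[!hub_gone] == 0.5))
})

test_that("an edgeless graph has a robustness curve identically zero", {
  g <- igraph::make_empty_graph(8, directed = FALSE)
  rc <- robustness_curve(g, c(0.2, 0.5, 0.8), n_reps = 20, seed = 1)
  expect_equal(rc$mean, c(0, 0, 0))
})

test_that("Monte-Carlo mean agrees with exhaustive enumeration on 6-node graphs", {
  set.seed(61)
  for (i in 1:3) {
    g <- igraph::sample_gnp(6, 0.5)
    adj <- igraph::as_adjacency_matrix(g, sparse = FALSE) > 0
    exact <- oracle_robustness_mean(adj, 3L)  # all C(6,3) = 20 removal sets
    pt <- robustness_random_removal(g, 0.5, n_reps = 2000, seed = 100 + i)
    se <- pt$sd / sqrt(pt$n_reps)
    expect_lte(abs(pt$mean - exact), max(3 * se, 1e-12))
  }
})

test_that("replicate counts respect the unremoved-share bound", {
  set.seed(4)
  g <- igraph::sample_gnp(20, 0.3)
  for (f in c(0.25, 0.5, 0.75)) {
    pt <- robustness_random_removal(g, f, n_reps = 100, seed = 5)
    expect_true(all(pt$replicates >= 0 & pt$replicates <= 1))
    expect_true(all(pt$replicates <= 1 - f + 1 / igraph::gorder(g) + 1e-12))
  }
})

test_that("robustness curves are seed-deterministic and decrease for connected graphs", {
  g <- igraph::sample_gnp(30, 0.3)
  rc1 <- robustness_curve(g, seq(0.1, 0.9, 0.2), n_reps = 2000, seed = 42)
  rc2 <- robustness_curve(g, seq(0.1, 0.9, 0.2), n_reps = 2000, seed = 42)
  expect_identical(rc1$mean, rc2$mean)
  expect_true(all(diff(rc1$mean) < 0.02))  # non-increasing up to MC noise
  expect_error(robustness_curve(g, c(0.5, 0.4), n_reps = 5, seed = 1),
               "increasing")
  expect_error(robustness_random_removal(g, 1.2, n_reps = 5, seed = 1),
               "strictly in")
})

test_that("robustness is invariant under node relabeling", {
  set.seed(17)
  g <- igraph::sample_gnp(15, 0.25)
  igraph::V(g)$name <- paste0("n", 1:15)
  perm <- sample(15)
  g2 <- igraph::permute(g, perm)
  r1 <- robustness_random_removal(g, 0.5, n_reps = 600, seed = 21)
  r2 <- robustness_random_removal(g2, 0.5, n_reps = 600, seed = 22)
  ks <- suppressWarnings(stats::ks.test(r1$replicates, r2$replicates))
  expect_gt(ks$p.value, 0.01)
})

test_that("denser planted scenarios give more robust networks", {
  diff_means <- vapply(1:5, function(seed) {
    nets <- lapply(c(2, 6), function(nb) {
      sc <- sim_scenario(n_otus = 40, days = 1:20, n_ports = 5,
                         stage_boundary_day = 99, n_blocks_high = nb,
                         n_blocks_low = 0, block_size = 4,
                         nutrient_blocks = FALSE, sequencing_depth = 3000)
      cooccurrence_network(simulate_counts(sc, seed = seed)$table)
    })
    vapply(nets, function(nt)
      robustness_random_removal(nt, 0.5, n_reps = 300, seed = seed)$mean,
      numeric(1))
  }, numeric(2))
  expect_gt(mean(diff_means[2, ] - diff_means[1, ]), 0)
})

test_that("alternative remaining-node definitions are available", {
  g <- igraph::make_full_graph(10)
  surv <- robustness_random_removal(g, 0.5, n_reps = 20, seed = 2,
                                    denominator = "survivors")
  expect_true(all(surv$replicates == 1))
  lcc <- robustness_random_removal(g, 0.5, n_reps = 20, seed = 2,
                                   measure = "lcc")
  expect_true(all(lcc$replicates == 0.5))
})
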