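test_that("generator is reproducible and samples sum to sequencing depth", {
  sc <- tiny_scenario()
  sim1 <- simulate_counts(sc, seed = 11)
  sim2 <- simulate_counts(sc, seed = 11)
  expect_identical(sim1, sim2)
  expect_true(all(colSums(sim1$table$counts) == sc$sequencing_depth))
  expect_equal(nrow(sim1$table$metadata),
               length(sc$days) * sc$n_ports)  # one sample per (day, port)

  sim3 <- simulate_counts(sc, seed = 12)
  expect_false(identical(sim1$table$counts, sim3$table$counts))
})

test_that("scenario validation rejects inconsistent block specs", {
  expect_error(sim_scenario(n_otus = 10), "exceeding n_otus")
  expect_error(tiny_scenario(block_rho = 1.2), "strictly in")
  bad <- data.frame(size = 3, rho = 0.8, sign = 1, stage = "mid",
                    driver = "none")
  expect_error(tiny_scenario(block_spec = bad), "stage")
})

test_that("zero planted blocks yield an empty ground truth", {
  sc <- tiny_scenario(block_spec = data.frame(size = integer(), rho = numeric(),
                                              sign = numeric(),
                                              stage = character(),
                                              driver = character()))
  sim <- simulate_counts(sc, seed = 3)
  expect_equal(nrow(sim$truth$edges), 0L)
})

test_that("ground truth lists exactly the within-block pairs, no self-pairs", {
  sc <- tiny_scenario()
  sim <- simulate_counts(sc, seed = 5)
  e <- sim$truth$edges
  expect_true(all(e$otu_a != e$otu_b))
  expect_true(all(e$sign %in% c(-1, 1)))
  expect_equal(nrow(e), sum(choose(sc$block_spec$size, 2)))
  # boundary-day samples belong to the low stage
  st <- sim$truth$stage_of_sample
  meta <- sim$table$metadata
  expect_identical(unname(st[meta$sample]),
                   ifelse(meta$day >= sc$stage_boundary_day, "low", "high"))
})

test_that("a planted high-correlation pair is recovered above the rho threshold", {
  sc <- sim_scenario(n_otus = 20, days = 1:40, n_ports = 5,
                     stage_boundary_day = 99,
                     block_spec = data.frame(size = 2, rho = 0.95, sign = 1,
                                             stage = "high", driver = "none"),
                     sequencing_depth = 5000, nutrient_blocks = FALSE)
  sim <- simulate_counts(sc, seed = 21)  # 200 samples, one planted pair
  m <- relative_abundance(sim$table)
  pair <- c(sim$truth$edges$otu_a[1], sim$truth$edges$otu_b[1])
  rho_pkg <- spearman_all_pairs(m[pair, ])$rho[1, 2]
  rho_oracle <- oracle_spearman(m[pair[1], ], m[pair[2], ])
  expect_equal(rho_pkg, rho_oracle, tolerance = 1e-12)
  expect_gt(rho_pkg, 0.6)
})

test_that("negative sign-split blocks plant negative observed correlations", {
  sc <- sim_scenario(n_otus = 12, days = 1:30, n_ports = 5,
                     stage_boundary_day = 99,
                     block_spec = data.frame(size = 4, rho = 0.9, sign = -1,
                                             stage = "high", driver = "none"),
                     sequencing_depth = 5000, nutrient_blocks = FALSE)
  sim <- simulate_counts(sc, seed = 9)
  m <- relative_abundance(sim$table)
  e <- sim$truth$edges
  rho <- spearman_all_pairs(m)$rho
  obs_sign <- sign(rho[cbind(e$otu_a, e$otu_b)])
  expect_identical(obs_sign, e$sign)
  expect_true(any(e$sign == -1) && any(e$sign == 1))
})

test_that("positive diversity shift raises low-stage Shannon diversity", {
  for (seed in 1:3) {
    sc <- sim_scenario(n_otus = 60, days = 1:40, n_ports = 5,
                       stage_boundary_day = 21, diversity_shift = 0.25,
                       n_blocks_high = 2, n_blocks_low = 2, block_size = 4,
                       nutrient_blocks = FALSE, sequencing_depth = 5000)
    sim <- simulate_counts(sc, seed = seed)  # 100 samples per stage
    d <- alpha_diversity(sim$table, "shannon")
    expect_gt(mean(d$value[d$stage == "low"]),
              mean(d$value[d$stage == "high"]))
  }
})

test_that("nutrient curves ramp, plateau at 150 mg/L TS, and step down", {
  sc <- sim_scenario(nutrient_noise_sd = 0)
  nut <- simulate_nutrients(sc, seed = 1)
  # port SP2 has zero lag: plateau reached after the 17-day ramp
  sp2 <- nut[nut$port == "SP2", ]
  expect_equal(sp2$TS[sp2$day == 30], 150)
  expect_true(all(sp2$TS[sp2$day >= 17 & sp2$day <= 40] == 150))
  expect_true(all(sp2$TS[sp2$day < 17] < 150))
  # after the stage boundary passes a port (boundary + lag), TS drops
  for (i in seq_along(sc$ports)) {
    pp <- nut[nut$port == sc$ports[i], ]
    after <- pp$day > sc$stage_boundary_day + sc$port_lag[i]
    expect_true(all(pp$TS[after] < 150))
    expect_true(all(pp$TS[after] == 75))
  }
  expect_true(all(nut$TS >= 0 & nut$TN >= 0 & nut$TP >= 0))
  expect_false(anyDuplicated(nut[, c("day", "port")]) > 0)
})

test_that("later ports lag earlier ports; zero lag makes ports identical", {
  sc <- sim_scenario()
  nut <- simulate_nutrients(sc, seed = 2)
  # the lagged port is still ramping when the first port has plateaued
  first <- nut[nut$port == "SP2", ]
  last <- nut[nut$port == "SP10", ]
  expect_true(mean(last$TS[last$day <= 20]) < mean(first$TS[first$day <= 20]))

  sc0 <- sim_scenario(port_lag = rep(0L, 7))
  nut0 <- simulate_nutrients(sc0, seed = 2)
  by_port <- split(nut0[, c("TS", "TN", "TP")], nut0$port)
  for (b in by_port) expect_equal(unname(as.matrix(b)),
                                  unname(as.matrix(by_port[[1]])))
})

test_that("simulation round-trips through TSV files", {
  sim <- simulate_community(tiny_scenario(), seed = 4)
  dir <- withr::local_tempdir()
  paths <- write_simulation(sim, dir)
  back <- read_otu_table(paths[["otu_table"]], paths[["metadata"]],
                         paths[["taxonomy"]])
  expect_equal(back$counts, sim$table$counts)
  expect_equal(back$metadata, sim$table$metadata)
  expect_equal(back$taxonomy, sim$table$taxonomy)
  nut <- read_nutrients(paths[["nutrients"]])
  expect_equal(nut$TS, sim$nutrients$TS, tolerance = 1e-8)
})
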