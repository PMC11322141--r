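#' Simulation scenario for a two-stage nutrient-injection experiment
#'
#' Describes a synthetic long-core flooding experiment: one sample per
#' (day, sampling port), a high-nutrient stage up to `stage_boundary_day`
#' (exclusive) and a low-nutrient stage from that day on, planted inter-OTU
#' correlation blocks, and port-lagged nutrient concentration curves
#' (total sugars TS, total nitrogen TN, total phosphorus TP, mg/L).
#'
#' Planted structure is organised in single-factor blocks. Each block has a
#' latent factor; members load on it with loading `+-sqrt(rho)`, so every
#' within-block pair has latent correlation `+-rho`. A block with
#' `sign = -1` splits its members into a positively and a negatively loading
#' half, planting negative associations across the split (a block in which
#' every pair is strongly negatively correlated would not be positive
#' definite). A block may be active in one stage only (`stage = "high"` or
#' `"low"`; members are plain noise in the other stage) or in `"both"`.
#' Blocks with a `driver` of `"TS"`, `"TN"` or `"TP"` replace the latent
#' factor by Gaussian scores of the port's measured nutrient concentration,
#' planting nutrient-OTU associations.
#'
#' When `block_spec` is `NULL` a default design is built: `n_blocks_high`
#' blocks active in the high stage and `n_blocks_low` in the low stage (all of
#' size `block_size` at latent correlation `block_rho`), with the fraction of
#' negative blocks per stage taken from `negative_fraction_by_stage`, plus one
#' TN-driven and one TS-driven block active in both stages. The defaults give
#' the low stage more planted connectivity and fewer negative associations
#' than the high stage, together with a positive evenness shift
#' (`diversity_shift`).
#'
#' @param n_otus total number of OTUs (default 150).
#' @param n_ports number of sampling ports (default 7).
#' @param ports port labels; default `SP2, SP3, SP4, SP5, SP6, SP7, SP10`
#'   (first `n_ports` of them; generic labels beyond 7).
#' @param days sampling days (default `1:60`).
#' @param stage_boundary_day first day of the low-nutrient stage (default 40;
#'   samples on the boundary day belong to the low stage).
#' @param block_spec data.frame with columns `size`, `rho` (in (0,1)), `sign`
#'   (+1/-1), `stage` (`"high"`, `"low"`, `"both"`), `driver` (`"none"`,
#'   `"TS"`, `"TN"`, `"TP"`); or `NULL` for the default design.
#' @param n_blocks_high,n_blocks_low,block_size,block_rho parameters of the
#'   default block design.
#' @param negative_fraction_by_stage named numeric `c(high=, low=)`: target
#'   fraction of per-stage blocks that are sign-split (negative), default
#'   `c(high = 0.4, low = 0.15)`.
#' @param nutrient_blocks logical; include the TN- and TS-driven blocks in the
#'   default design (default TRUE).
#' @param sequencing_depth reads per sample (default 50000).
#' @param dispersion standard deviation of the latent log-abundance layer
#'   (default 1).
#' @param base_sd standard deviation of per-OTU baseline log abundances;
#'   controls community unevenness (default 1).
#' @param diversity_shift in `[0, 1)`: low-stage baseline log-abundance spread
#'   is scaled by `1 - diversity_shift`, raising low-stage evenness and hence
#'   Shannon diversity when positive (default 0.25).
#' @param port_lag integer day lag per port (default `0:(n_ports-1)`; the
#'   nutrient front reaches later ports later).
#' @param ts_plateau,tn_plateau,tp_plateau named numeric `c(high=, low=)`
#'   plateau concentrations in mg/L; defaults TS 150/75, TN 60/30, TP 30/15
#'   (low plateaus are half the high ones, mirroring a halved feed recipe).
#' @param ts_ramp_days,tn_ramp_days,tp_ramp_days days for the concentration to
#'   ramp from 0 to the high plateau (defaults 17, 8, 8).
#' @param nutrient_noise_sd lognormal fluctuation (sd on the log scale) of the
#'   injected batch concentration, shared by all ports at equal effective day
#'   (default 0.05).
#' @param seed default RNG seed used by the generator functions (default 1).
#'
#' @return object of class `sim_scenario`.
#' @export
sim_scenario <- function(n_otus = 150,
                         n_ports = 7,
                         ports = NULL,
                         days = 1:60,
                         stage_boundary_day = 40,
                         block_spec = NULL,
                         n_blocks_high = 8,
                         n_blocks_low = 12,
                         block_size = 5,
                         block_rho = 0.8,
                         negative_fraction_by_stage = c(high = 0.4, low = 0.15),
                         nutrient_blocks = TRUE,
                         sequencing_depth = 50000,
                         dispersion = 1,
                         base_sd = 1,
                         diversity_shift = 0.25,
                         port_lag = NULL,
                         ts_plateau = c(high = 150, low = 75),
                         tn_plateau = c(high = 60, low = 30),
                         tp_plateau = c(high = 30, low = 15),
                         ts_ramp_days = 17,
                         tn_ramp_days = 8,
                         tp_ramp_days = 8,
                         nutrient_noise_sd = 0.05,
                         seed = 1) {
  if (!is_count(n_otus) || !is_count(n_ports) || !is_count(sequencing_depth))
    stopf("n_otus, n_ports and sequencing_depth must be positive integers")
  if (is.null(ports)) {
    std <- c("SP2", "SP3", "SP4", "SP5", "SP6", "SP7", "SP10")
    ports <- if (n_ports <= length(std)) std[seq_len(n_ports)]
             else c(std, paste0("SPx", seq_len(n_ports - length(std))))
  }
  if (length(ports) != n_ports) stopf("`ports` must have length n_ports")
  if (is.null(port_lag)) port_lag <- 0:(n_ports - 1L)
  if (length(port_lag) != n_ports) stopf("`port_lag` must have length n_ports")
  days <- sort(unique(as.integer(days)))
  if (any(days < 1)) stopf("`days` must be positive")
  if (!is.numeric(dispersion) || dispersion <= 0)
    stopf("`dispersion` must be positive")
  if (diversity_shift < 0 || diversity_shift >= 1)
    stopf("`diversity_shift` must be in [0, 1)")
  nf <- negative_fraction_by_stage
  if (is.null(names(nf)) || !all(c("high", "low") %in% names(nf)) ||
      any(nf < 0 | nf > 1))
    stopf("`negative_fraction_by_stage` must be c(high=, low=) in [0, 1]")

  if (is.null(block_spec)) {
    mk <- function(n, stage, frac_neg) {
      if (n == 0) return(NULL)
      n_neg <- round(n * frac_neg)
      data.frame(size = block_size, rho = block_rho,
                 sign = c(rep(-1, n_neg), rep(1, n - n_neg)),
                 stage = stage, driver = "none", stringsAsFactors = FALSE)
    }
    block_spec <- rbind(
      mk(n_blocks_high, "high", nf[["high"]]),
      mk(n_blocks_low, "low", nf[["low"]]),
      if (nutrient_blocks)
        data.frame(size = block_size, rho = 0.85, sign = 1, stage = "both",
                   driver = c("TN", "TS"), stringsAsFactors = FALSE))
  }
  block_spec <- as.data.frame(block_spec, stringsAsFactors = FALSE)
  req <- c("size", "rho", "sign", "stage", "driver")
  miss <- setdiff(req, names(block_spec))
  if (length(miss)) stopf("block_spec lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (nrow(block_spec)) {
    if (any(block_spec$size < 2))
      stopf("block sizes must be at least 2")
    if (any(block_spec$rho <= 0 | block_spec$rho >= 1))
      stopf("within-block correlations must lie strictly in (0, 1)")
    if (!all(block_spec$sign %in% c(-1, 1)))
      stopf("block signs must be +1 or -1")
    if (!all(block_spec$stage %in% c("high", "low", "both")))
      stopf("block stage must be 'high', 'low' or 'both'")
    if (!all(block_spec$driver %in% c("none", "TS", "TN", "TP")))
      stopf("block driver must be 'none', 'TS', 'TN' or 'TP'")
    if (sum(block_spec$size) > n_otus)
      stopf("block sizes sum to %d, exceeding n_otus = %d",
            sum(block_spec$size), n_otus)
  }

  sc <- list(n_otus = n_otus, n_ports = n_ports, ports = ports, days = days,
             stage_boundary_day = as.integer(stage_boundary_day),
             block_spec = block_spec,
             negative_fraction_by_stage = nf,
             sequencing_depth = sequencing_depth,
             dispersion = dispersion, base_sd = base_sd,
             diversity_shift = diversity_shift,
             port_lag = as.integer(port_lag),
             ts_plateau = ts_plateau, tn_plateau = tn_plateau,
             tp_plateau = tp_plateau,
             ts_ramp_days = ts_ramp_days, tn_ramp_days = tn_ramp_days,
             tp_ramp_days = tp_ramp_days,
             nutrient_noise_sd = nutrient_noise_sd,
             seed = as.integer(seed))
  class(sc) <- "sim_scenario"
  sc
}

#' @export
print.sim_scenario <- function(x, ...) {
  cat(sprintf("Simulation scenario: %d OTUs, %d ports x %d days (%d samples)\n",
              x$n_otus, x$n_ports, length(x$days),
              x$n_ports * length(x$days)))
  cat(sprintf("  low stage from day %d; depth %d; %d planted blocks\n",
              x$stage_boundary_day, x$sequencing_depth, nrow(x$block_spec)))
  invisible(x)
}

# stage of a sample: boundary day belongs to the low-nutrient stage
stage_of_day <- function(day, boundary) ifelse(day >= boundary, "low", "high")

# piecewise base concentration at effective (lag-corrected) day
nutrient_base <- function(eff_day, plateau, ramp_days, boundary) {
  out <- numeric(length(eff_day))
  up <- eff_day > 0 & eff_day < ramp_days
  hi <- eff_day >= ramp_days & eff_day <= boundary
  lo <- eff_day > boundary
  out[up] <- plateau[["high"]] * eff_day[up] / ramp_days
  out[hi] <- plateau[["high"]]
  out[lo] <- plateau[["low"]]
  out
}

#' Generate the nutrient concentration series of a scenario
#'
#' Produces one record per (day, port) with TS, TN and TP concentrations in
#' mg/L. Curves ramp from zero to a high-stage plateau, hold it until the
#' reduced feed reaches the port, then step down to the low plateau; each
#' port lags the injection end by its `port_lag`. A multiplicative lognormal
#' fluctuation is applied per effective day (the injected batch varies), so
#' all ports see the same fluctuated batch at equal effective day and
#' zero-lag ports have identical curves.
#'
#' @param scenario `sim_scenario`.
#' @param seed RNG seed; defaults to the scenario's.
#' @return data.frame of class `nutrient_series` with columns `day`, `port`,
#'   `TS`, `TN`, `TP`.
#' @export
simulate_nutrients <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  max_day <- max(sc$days)
  noise <- with_seed(child_seed(seed, 1L), {
    matrix(exp(stats::rnorm(3L * max_day, 0, sc$nutrient_noise_sd)),
           nrow = max_day, ncol = 3L,
           dimnames = list(NULL, c("TS", "TN", "TP")))
  })
  grid <- expand.grid(port_idx = seq_len(sc$n_ports), day = sc$days,
                      KEEP.OUT.ATTRS = FALSE)
  eff <- grid$day - sc$port_lag[grid$port_idx]
  val <- function(nut, plateau, ramp) {
    base <- nutrient_base(eff, plateau, ramp, sc$stage_boundary_day)
    fl <- rep(1, length(eff))
    ok <- eff >= 1
    fl[ok] <- noise[eff[ok], nut]
    base * fl
  }
  out <- data.frame(day = grid$day, port = sc$ports[grid$port_idx],
                    TS = val("TS", sc$ts_plateau, sc$ts_ramp_days),
                    TN = val("TN", sc$tn_plateau, sc$tn_ramp_days),
                    TP = val("TP", sc$tp_plateau, sc$tp_ramp_days),
                    stringsAsFactors = FALSE)
  out <- out[order(out$day, match(out$port, sc$ports)), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("nutrient_series", "data.frame")
  out
}

# deterministic synthetic lineage strings for the generated OTUs
synthetic_taxonomy <- function(otu_ids, seed) {
  phyla <- c("Proteobacteria", "Firmicutes", "Bacteroidota", "Spirochaetota",
             "Desulfobacterota", "Thermotogota", "Cloacimonadota")
  genera <- list(
    Proteobacteria = c("Pseudomonas", "Vibrio", "Marinobacter"),
    Firmicutes = c("Exiguobacterium", "Enterococcus", "Bacillus",
                   "Clostridium"),
    Bacteroidota = c("Macellibacteroides", "Proteiniphilum"),
    Spirochaetota = c("Sphaerochaeta", "Treponema"),
    Desulfobacterota = c("Desulfovibrio", "Desulfomicrobium"),
    Thermotogota = c("Petrotoga", "Defluviitoga"),
    Cloacimonadota = c("Cloacimonas", "LNR_A2-18"))
  with_seed(child_seed(seed, 5L), {
    ph <- sample(phyla, length(otu_ids), replace = TRUE)
    ge <- vapply(ph, function(p) sample(genera[[p]], 1L), character(1))
    stats::setNames(sprintf("k__Bacteria; p__%s; g__%s_%s",
                            ph, ge, seq_along(otu_ids)), otu_ids)
  })
}

# block bookkeeping: member indices and per-member loading signs
block_layout <- function(scenario) {
  bs <- scenario$block_spec
  if (!nrow(bs)) return(NULL)
  start <- cumsum(c(1L, bs$size))[seq_len(nrow(bs))]
  lapply(seq_len(nrow(bs)), function(b) {
    members <- start[b]:(start[b] + bs$size[b] - 1L)
    signs <- rep(1, bs$size[b])
    if (bs$sign[b] < 0) {
      n_neg <- floor(bs$size[b] / 2)
      signs[seq_len(n_neg)] <- -1
    }
    list(members = members, signs = signs, rho = bs$rho[b],
         stage = bs$stage[b], driver = bs$driver[b])
  })
}

#' Generate an OTU count table with planted structure
#'
#' Draws counts through a latent-Gaussian (copula) layer: a standard-normal
#' latent variable per OTU and sample, correlated within planted blocks via a
#' one-factor model, is mapped through a log-normal transform onto heavy-
#' tailed expected abundances and each sample is drawn from a multinomial at
#' `sequencing_depth` reads. Because Spearman correlation is invariant to the
#' monotone marginal transform, the planted latent rank correlations are what
#' the downstream network pipeline measures. Low-stage samples have their
#' baseline log-abundance spread shrunk by `1 - diversity_shift`, raising
#' their evenness.
#'
#' @param scenario `sim_scenario`.
#' @param seed RNG seed; defaults to the scenario's. Identical
#'   (scenario, seed) pairs reproduce the table exactly.
#' @return list with elements `table` (an [otu_table()] including synthetic
#'   taxonomy) and `truth` (a `ground_truth` object: planted edges with sign
#'   and stage, the stage of every sample, and the block layout).
#' @export
simulate_counts <- function(scenario, seed = scenario$seed) {
  stopifnot(inherits(scenario, "sim_scenario"))
  sc <- scenario
  nutr <- simulate_nutrients(sc, seed)

  grid <- expand.grid(port_idx = seq_len(sc$n_ports), day = sc$days,
                      KEEP.OUT.ATTRS = FALSE)
  grid <- grid[order(grid$day, grid$port_idx), , drop = FALSE]
  n <- nrow(grid)
  p <- sc$n_otus
  sample_ids <- sprintf("d%02d_%s", grid$day, sc$ports[grid$port_idx])
  stage <- stage_of_day(grid$day, sc$stage_boundary_day)
  otu_ids <- sprintf("OTU%04d", seq_len(p))

  base_mean <- with_seed(child_seed(seed, 2L), stats::rnorm(p, 0, sc$base_sd))
  z <- with_seed(child_seed(seed, 3L),
                 matrix(stats::rnorm(n * p), nrow = n, ncol = p))

  layout <- block_layout(sc)
  nut_key <- paste(nutr$day, nutr$port)
  samp_key <- paste(grid$day, sc$ports[grid$port_idx])
  nut_row <- match(samp_key, nut_key)
  if (length(layout)) {
    factors <- with_seed(child_seed(seed, 4L),
                         matrix(stats::rnorm(n * length(layout)), nrow = n))
    for (b in seq_along(layout)) {
      bl <- layout[[b]]
      f <- if (bl$driver == "none") {
        factors[, b]
      } else {
        v <- nutr[[bl$driver]][nut_row]
        # Gaussian scores of the measured concentration: monotone in v,
        # standard-normal marginal, so the copula layer stays calibrated
        stats::qnorm((rank(v, ties.method = "average") - 0.5) / n)
      }
      active <- if (bl$stage == "both") rep(TRUE, n) else stage == bl$stage
      a <- bl$signs * sqrt(bl$rho)
      z[active, bl$members] <-
        outer(f[active], a) +
        sqrt(1 - bl$rho) * z[active, bl$members, drop = FALSE]
    }
  }

  even_scale <- ifelse(stage == "low", 1 - sc$diversity_shift, 1)
  log_lambda <- outer(even_scale, base_mean) + sc$dispersion * z
  counts <- with_seed(child_seed(seed, 6L), {
    out <- matrix(0, nrow = p, ncol = n)
    for (i in seq_len(n)) {
      w <- exp(log_lambda[i, ] - max(log_lambda[i, ]))
      out[, i] <- stats::rmultinom(1L, sc$sequencing_depth, w / sum(w))
    }
    out
  })
  dimnames(counts) <- list(otu_ids, sample_ids)

  meta <- data.frame(sample = sample_ids, day = grid$day,
                     port = sc$ports[grid$port_idx], stage = stage,
                     stringsAsFactors = FALSE)
  tab <- otu_table(counts, meta, synthetic_taxonomy(otu_ids, seed))

  edges <- NULL
  if (length(layout)) {
    edges <- do.call(rbind, lapply(layout, function(bl) {
      pr <- utils::combn(seq_along(bl$members), 2L)
      data.frame(otu_a = otu_ids[bl$members[pr[1L, ]]],
                 otu_b = otu_ids[bl$members[pr[2L, ]]],
                 sign = bl$signs[pr[1L, ]] * bl$signs[pr[2L, ]],
                 stage = bl$stage, driver = bl$driver,
                 stringsAsFactors = FALSE)
    }))
  } else {
    edges <- data.frame(otu_a = character(), otu_b = character(),
                        sign = numeric(), stage = character(),
                        driver = character(), stringsAsFactors = FALSE)
  }
  truth <- structure(
    list(edges = edges,
         stage_of_sample = stats::setNames(stage, sample_ids),
         blocks = layout, otu_ids = otu_ids),
    class = "ground_truth")
  list(table = tab, truth = truth)
}

#' Planted edges active in a given stage
#'
#' @param truth `ground_truth` from [simulate_counts()].
#' @param stage `"high"`, `"low"`, or `"any"` (all planted edges).
#' @return data.frame with columns `otu_a`, `otu_b`, `sign`.
#' @export
planted_edges <- function(truth, stage = c("any", "high", "low")) {
  stopifnot(inherits(truth, "ground_truth"))
  stage <- match.arg(stage)
  e <- truth$edges
  if (stage != "any") e <- e[e$stage %in% c(stage, "both"), , drop = FALSE]
  e[, c("otu_a", "otu_b", "sign")]
}

#' Run the full generator: counts, ground truth and nutrients
#'
#' @param scenario `sim_scenario`.
#' @param seed RNG seed; defaults to the scenario's.
#' @return list of class `community_sim` with elements `table`, `truth`,
#'   `nutrients`, `scenario`, `seed`.
#' @export
simulate_community <- function(scenario, seed = scenario$seed) {
  cg <- simulate_counts(scenario, seed)
  structure(list(table = cg$table, truth = cg$truth,
                 nutrients = simulate_nutrients(scenario, seed),
                 scenario = scenario, seed = as.integer(seed)),
            class = "community_sim")
}

#' Write a simulated data set to TSV files
#'
#' Writes the OTU table, sample metadata, taxonomy, nutrient series and the
#' planted ground-truth edge list into `dir` (created if needed).
#'
#' @param sim `community_sim` from [simulate_community()].
#' @param dir output directory.
#' @return invisibly, the named vector of file paths written.
#' @export
write_simulation <- function(sim, dir) {
  stopifnot(inherits(sim, "community_sim"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- c(otu_table = file.path(dir, "otu_table.tsv"),
             metadata = file.path(dir, "metadata.tsv"),
             taxonomy = file.path(dir, "taxonomy.tsv"),
             nutrients = file.path(dir, "nutrients.tsv"),
             truth = file.path(dir, "planted_edges.tsv"))
  write_otu_table(sim$table, paths[["otu_table"]], paths[["metadata"]],
                  paths[["taxonomy"]])
  utils::write.table(as.data.frame(sim$nutrients), paths[["nutrients"]],
                     sep = "\t", quote = FALSE, row.names = FALSE)
  utils::write.table(sim$truth$edges, paths[["truth"]], sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(paths)
}

#' Read a nutrient series from TSV
#'
#' @param path TSV with columns `day`, `port`, `TS`, `TN`, `TP`.
#' @return `nutrient_series` data.frame.
#' @export
read_nutrients <- function(path) {
  if (!file.exists(path)) stopf("nutrient file not found: %s", path)
  out <- utils::read.table(path, header = TRUE, sep = "\t",
                           stringsAsFactors = FALSE)
  req <- c("day", "port", "TS", "TN", "TP")
  miss <- setdiff(req, names(out))
  if (length(miss)) stopf("nutrient file lacks column(s): %s",
                          paste(miss, collapse = ", "))
  if (any(out[, c("TS", "TN", "TP")] < 0))
    stopf("nutrient concentrations must be non-negative")
  if (anyDuplicated(out[, c("day", "port")]))
    stopf("duplicate (day, port) records in nutrient file")
  class(out) <- c("nutrient_series", "data.frame")
  out
}
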