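#' Default pipeline configuration
#'
#' Returns the full configuration list of [run_pipeline()] with defaults
#' filled in; any supplied entries override them. See Details for fields.
#'
#' @details
#' Fields: `seed` (master seed); `scenario` (list of [sim_scenario()]
#' arguments, or NULL with `input` set); `input` (list of file paths:
#' `otu_table`, `metadata`, `taxonomy`, `nutrients`); `rarefy_depth` (41051,
#' NULL to skip); `filter_threshold` (1e-4); `diversity_metric` ("shannon");
#' `group_by` ("window", "day" or "stage"); `windows_per_stage` (4);
#' `rho_threshold` (0.6); `alpha` (0.01); `use_adjusted` (TRUE);
#' `with_nutrients` (TRUE: additionally build one nutrient-OTU network per
#' stage); `robustness_fraction` (0.5); `robustness_reps` (1000);
#' `out_dir` (NULL: nothing written).
#'
#' @param config partial configuration list (or NULL).
#' @return complete configuration list.
#' @export
pipeline_config <- function(config = NULL) {
  defaults <- list(seed = 1L, scenario = list(), input = NULL,
                   rarefy_depth = 41051, filter_threshold = 1e-4,
                   diversity_metric = "shannon",
                   group_by = "window", windows_per_stage = 4L,
                   rho_threshold = 0.6, alpha = 0.01, use_adjusted = TRUE,
                   with_nutrients = TRUE,
                   robustness_fraction = 0.5, robustness_reps = 1000L,
                   out_dir = NULL)
  config <- config %||% list()
  unknown <- setdiff(names(config), names(defaults))
  if (length(unknown))
    stopf("unknown config field(s): %s", paste(unknown, collapse = ", "))
  utils::modifyList(defaults, config, keep.null = TRUE)
}

# split each stage's days into contiguous windows -> named list of day sets
day_windows <- function(days, stages, k) {
  out <- list()
  for (st in c("high", "low")) {
    d <- sort(unique(days[stages == st]))
    if (!length(d)) next
    kk <- min(k, length(d))
    chunks <- split(d, cut(seq_along(d), kk, labels = FALSE))
    for (i in seq_along(chunks))
      out[[sprintf("%s_w%d", st, i)]] <-
        list(days = chunks[[i]], stage = st)
  }
  out
}

#' Run the full co-occurrence analysis pipeline
#'
#' Orchestrates the end-to-end analysis: obtain data (synthetic scenario or
#' TSV inputs), rarefy, compute per-sample alpha diversity, filter
#' low-abundance OTUs, fit one co-occurrence network per sample group,
#' summarise topology, measure robustness under random node removal,
#' optionally fit per-stage nutrient-OTU networks, and test
#' high-versus-low-stage differences in diversity, negative-edge fraction and
#' robustness. With `out_dir` set, all tables, GraphML files and a run
#' manifest (file digests, seed, package version) are written; re-running
#' with an identical configuration reproduces the outputs byte for byte.
#'
#' @param config configuration list (see [pipeline_config()]) or the path to
#'   a YAML file holding one.
#' @return object of class `conet_pipeline`: list with `config`, `table`
#'   (preprocessed `otu_table`), `diversity`, `networks` (list of `conet`),
#'   `topology` (one row per network), `robustness` (per-network summary at
#'   the configured fraction), `nutrient_networks`, `comparisons`
#'   (data.frame of stage tests), `directions` (logical: `diversity_up`,
#'   `negative_down`, `robustness_up` in the low stage), and `manifest`.
#' @export
run_pipeline <- function(config = NULL) {
  if (is.character(config)) {
    if (!file.exists(config)) stopf("config file not found: %s", config)
    config <- yaml::read_yaml(config)
  }
  cfg <- pipeline_config(config)
  seed <- as.integer(cfg$seed)

  # --- inputs -------------------------------------------------------------
  truth <- NULL
  if (!is.null(cfg$input)) {
    inp <- cfg$input
    for (f in c("otu_table", "metadata"))
      if (is.null(inp[[f]]))
        stopf("input configuration lacks '%s' path", f)
    if (cfg$with_nutrients && is.null(inp$nutrients))
      stopf("with_nutrients requested but no nutrient file given in input")
    tab <- read_otu_table(inp$otu_table, inp$metadata, inp$taxonomy)
    nutrients <- if (!is.null(inp$nutrients)) read_nutrients(inp$nutrients)
  } else {
    scenario <- do.call(sim_scenario, c(cfg$scenario, list(seed = seed)))
    sim <- simulate_community(scenario, seed)
    tab <- sim$table
    nutrients <- sim$nutrients
    truth <- sim$truth
  }

  # --- preprocessing ------------------------------------------------------
  if (!is.null(cfg$rarefy_depth))
    tab <- rarefy(tab, depth = cfg$rarefy_depth, seed = child_seed(seed, 101L))
  diversity <- alpha_diversity(tab, metric = cfg$diversity_metric)
  tab <- filter_low_abundance(tab, cfg$filter_threshold)

  # --- per-group networks ---------------------------------------------------
  meta <- tab$metadata
  groups <- switch(cfg$group_by,
    stage = {
      g <- list()
      for (st in intersect(c("high", "low"), unique(meta$stage)))
        g[[st]] <- list(days = unique(meta$day[meta$stage == st]), stage = st)
      g
    },
    day = {
      g <- list()
      for (d in sort(unique(meta$day)))
        g[[sprintf("day%02d", d)]] <-
          list(days = d, stage = meta$stage[match(d, meta$day)])
      g
    },
    window = day_windows(meta$day, meta$stage, cfg$windows_per_stage),
    stopf("unknown group_by '%s'", cfg$group_by))

  networks <- lapply(names(groups), function(nm) {
    gr <- groups[[nm]]
    sub <- subset_samples(tab, meta$sample[meta$day %in% gr$days])
    net <- cooccurrence_network(sub, rho_threshold = cfg$rho_threshold,
                                alpha = cfg$alpha,
                                use_adjusted = cfg$use_adjusted,
                                filter_threshold = NULL, label = nm)
    net$stage <- gr$stage
    net
  })
  names(networks) <- names(groups)

  topology <- do.call(rbind, lapply(networks, topology_summary))
  topology$stage <- vapply(networks, `[[`, character(1), "stage")
  rownames(topology) <- NULL

  robustness <- do.call(rbind, lapply(seq_along(networks), function(i) {
    pt <- robustness_random_removal(networks[[i]],
                                    fraction = cfg$robustness_fraction,
                                    n_reps = cfg$robustness_reps,
                                    seed = child_seed(seed, 200L + i))
    data.frame(network = names(networks)[i], stage = networks[[i]]$stage,
               fraction = pt$fraction, mean = pt$mean, sd = pt$sd,
               n_reps = pt$n_reps, stringsAsFactors = FALSE)
  }))

  nutrient_networks <- NULL
  if (isTRUE(cfg$with_nutrients) && !is.null(nutrients)) {
    nutrient_networks <- lapply(intersect(c("high", "low"),
                                          unique(meta$stage)), function(st) {
      sub <- subset_samples(tab, meta$sample[meta$stage == st])
      nutrient_network(sub, nutrients, rho_threshold = cfg$rho_threshold,
                       alpha = cfg$alpha, use_adjusted = cfg$use_adjusted,
                       filter_threshold = NULL,
                       label = paste0("nutrient_", st))
    })
    names(nutrient_networks) <- vapply(nutrient_networks, `[[`, character(1),
                                       "label")
  }

  # --- stage comparisons ----------------------------------------------------
  comparisons <- NULL
  directions <- NULL
  if (all(c("high", "low") %in% meta$stage)) {
    # with fewer than 3 networks per stage the means and direction are still
    # reported, but no test is run (p and label NA)
    safe_cmp <- function(high, low, metric) {
      if (length(high) >= 3L && length(low) >= 3L)
        return(as.data.frame(compare_stages(high, low, metric = metric)))
      data.frame(metric = metric, n_high = length(high), n_low = length(low),
                 mean_high = mean(high), mean_low = mean(low),
                 statistic = NA_real_, p_value = NA_real_,
                 label = NA_character_, stringsAsFactors = FALSE)
    }
    comparisons <- rbind(
      safe_cmp(diversity$value[diversity$stage == "high"],
               diversity$value[diversity$stage == "low"],
               cfg$diversity_metric),
      safe_cmp(topology$negative_fraction[topology$stage == "high"],
               topology$negative_fraction[topology$stage == "low"],
               "negative_fraction"),
      safe_cmp(robustness$mean[robustness$stage == "high"],
               robustness$mean[robustness$stage == "low"],
               "robustness_at_fraction"))
    directions <- c(
      diversity_up = comparisons$mean_low[1] > comparisons$mean_high[1],
      negative_down = comparisons$mean_low[2] < comparisons$mean_high[2],
      robustness_up = comparisons$mean_low[3] > comparisons$mean_high[3])
  }

  out <- structure(
    list(config = cfg, table = tab, diversity = diversity,
         networks = networks, topology = topology, robustness = robustness,
         nutrient_networks = nutrient_networks, comparisons = comparisons,
         directions = directions, truth = truth, manifest = NULL),
    class = "conet_pipeline")
  if (!is.null(cfg$out_dir)) out$manifest <- write_pipeline(out, cfg$out_dir)
  out
}

# write every pipeline artifact and return the manifest
write_pipeline <- function(res, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  paths <- character()
  p <- function(f) file.path(dir, f)
  wt <- function(df, f) {
    utils::write.table(df, p(f), sep = "\t", quote = FALSE, row.names = FALSE)
    paths <<- c(paths, p(f))
  }
  wt(res$diversity, "diversity.tsv")
  topo <- cbind(format(structure(res$topology,
                                 class = c("topology_summary", "data.frame"))),
                stage = res$topology$stage)
  wt(topo, "topology.tsv")
  wt(res$robustness, "robustness.tsv")
  if (!is.null(res$comparisons)) wt(res$comparisons, "comparisons.tsv")
  for (nm in names(res$networks)) {
    paths <- c(paths, write_network(
      res$networks[[nm]],
      edge_path = p(sprintf("edges_%s.tsv", nm)),
      node_path = p(sprintf("nodes_%s.tsv", nm)),
      graphml_path = p(sprintf("network_%s.graphml", nm))))
  }
  for (nm in names(res$nutrient_networks)) {
    paths <- c(paths, write_network(
      res$nutrient_networks[[nm]],
      edge_path = p(sprintf("edges_%s.tsv", nm)),
      graphml_path = p(sprintf("network_%s.graphml", nm))))
  }
  manifest <- list(
    package = "reservoirnet",
    version = as.character(utils::packageVersion("reservoirnet")),
    seed = res$config$seed,
    config = res$config[setdiff(names(res$config), "out_dir")],
    files = as.list(unname(tools::md5sum(paths))))
  names(manifest$files) <- basename(paths)
  yaml::write_yaml(manifest, p("manifest.yaml"))
  manifest
}

#' @export
print.conet_pipeline <- function(x, ...) {
  cat(sprintf("Co-occurrence pipeline run (seed %d): %d network(s)\n",
              x$config$seed, length(x$networks)))
  print(structure(x$topology, class = c("topology_summary", "data.frame")))
  if (!is.null(x$comparisons)) {
    cat("\nStage comparisons (high vs low):\n")
    print(x$comparisons, row.names = FALSE)
  }
  invisible(x)
}
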