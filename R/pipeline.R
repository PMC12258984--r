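# End-to-end orchestration: simulate (or load) inputs, filter, proximity
# test per seed category, subnetwork clustering + enrichment, regulon
# activity, with one global seed deterministically deriving every stage
# seed and a JSON run manifest. The manifest contains no wall-clock state,
# so two runs with the same config and seed produce byte-identical output
# trees.

pipeline_defaults <- function() {
  list(
    propagation = list(alpha = 0.5, tol = 1e-9, max_iter = 1000L,
                       normalization = "symmetric"),
    proximity = list(n_random = 1000L, exclude_seed_overlap = FALSE,
                     pvalue_convention = "plus_one"),
    filter = list(lfc_cut = 2, p_cut = 0.05, direction = "up",
                  use_q = FALSE),
    clustering = list(k = 3L, method = "average_linkage"),
    enrichment = list(top_k = 3L, fdr_family = "joint"),
    activity = list(n_perm = 1000L, min_targets = 3L)
  )
}

merge_defaults <- function(cfg, defaults) {
  for (nm in names(defaults)) {
    if (is.null(cfg[[nm]])) cfg[[nm]] <- defaults[[nm]]
    else if (is.list(defaults[[nm]]))
      cfg[[nm]] <- utils::modifyList(defaults[[nm]], cfg[[nm]])
  }
  cfg
}

#' Validate a pipeline run configuration
#'
#' Fills in defaults and checks every numeric constraint and referenced
#' file; all problems are reported together in a single aggregated error.
#' A configuration either carries a `simulate` block (synthetic inputs are
#' generated at run time) or an `inputs` block with file paths (`network`
#' plus optional `network_format`, a named list `seeds` of gene-list
#' files, `query_table` (DE TSV) or `query_list`, optional `gmt` and
#' `regulons`).
#'
#' @param cfg nested list, typically from `yaml::read_yaml()`.
#' @return the validated config with defaults materialized.
#' @export
validate_config <- function(cfg) {
  problems <- character(0)
  note <- function(fmt, ...) problems <<- c(problems, sprintf(fmt, ...))
  if (is.null(cfg$seed)) note("`seed` (global RNG seed) is required")
  else if (!is.numeric(cfg$seed) || cfg$seed != round(cfg$seed))
    note("`seed` must be an integer, got %s", deparse(cfg$seed))
  cfg <- merge_defaults(cfg, pipeline_defaults())
  p <- cfg$propagation
  if (!is.numeric(p$alpha) || p$alpha <= 0 || p$alpha >= 1)
    note("propagation alpha must lie in (0, 1), got %s", deparse(p$alpha))
  if (!is.numeric(p$tol) || p$tol < 0) note("propagation tol must be >= 0")
  if (!p$normalization %in% c("symmetric", "row"))
    note("propagation normalization must be 'symmetric' or 'row'")
  if (!is.numeric(cfg$proximity$n_random) || cfg$proximity$n_random < 1)
    note("proximity n_random must be >= 1")
  if (!cfg$proximity$pvalue_convention %in% c("plus_one", "rank_over_n"))
    note("proximity pvalue_convention must be 'plus_one' or 'rank_over_n'")
  f <- cfg$filter
  if (!is.numeric(f$lfc_cut) || f$lfc_cut < 0)
    note("filter lfc_cut must be >= 0")
  if (!is.numeric(f$p_cut) || f$p_cut <= 0 || f$p_cut > 1)
    note("filter p_cut must lie in (0, 1]")
  if (!f$direction %in% c("up", "down", "both"))
    note("filter direction must be 'up', 'down' or 'both'")
  if (!is.numeric(cfg$clustering$k) || cfg$clustering$k < 1)
    note("clustering k must be >= 1")
  if (is.null(cfg$simulate) && is.null(cfg$inputs))
    note("either a `simulate` block or an `inputs` block is required")
  if (!is.null(cfg$inputs)) {
    ins <- cfg$inputs
    if (is.null(ins$network)) note("inputs$network path is required")
    else if (!file.exists(ins$network))
      note("network file not found: %s", ins$network)
    for (nm in names(ins$seeds))
      if (!file.exists(ins$seeds[[nm]]))
        note("seed-list file not found (%s): %s", nm, ins$seeds[[nm]])
    for (fld in c("query_table", "query_list", "gmt", "regulons"))
      if (!is.null(ins[[fld]]) && !file.exists(ins[[fld]]))
        note("%s file not found: %s", fld, ins[[fld]])
  }
  if (length(problems))
    stopf("invalid configuration:\n%s",
          paste0("  - ", problems, collapse = "\n"))
  cfg
}

#' Built-in all-synthetic demo configuration
#'
#' A small modular network with one planted disease module, planted
#' seed/query sets at proximity 0.8, a DE table, a gene-set collection with
#' a planted term, and planted-active regulons.
#'
#' @param seed global seed.
#' @return a config list accepted by [run_all()].
#' @export
demo_config <- function(seed = 11L) {
  list(
    seed = as.integer(seed),
    simulate = list(
      network = list(block_sizes = c(30L, 35L, 35L), p_in = 0.25,
                     p_out = 0.02),
      sets = list(target_block = 1L, seed_size = 12L, query_size = 20L,
                  proximity = 0.8),
      de = list(n_features = 400L, frac_regulated = 0.2, effect_lfc = 3,
                n_replicates_per_group = 5L, sigma = 0.5),
      gmt = list(n_terms = 8L, term_size = 12L, planted_term_block = 1L),
      regulons = list(n_regulators = 10L, targets_per = 8L,
                      active_fraction = 0.3, effect_lfc = 2,
                      noise_sd = 0.1)
    ),
    proximity = list(n_random = 500L),
    clustering = list(k = 3L),
    activity = list(n_perm = 500L)
  )
}

write_tsv <- function(df, path) {
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full pipeline
#'
#' Stages: obtain inputs (simulate or load) -> DE threshold filter ->
#' proximity test per seed category -> induced subnetwork of the query
#' list -> hierarchical clustering -> per-cluster overrepresentation ->
#' regulon activity (skipped with a notice when no regulons are given).
#' All stage seeds derive from the global seed by stable name hashing, so
#' results are reproducible and stages are independent.
#'
#' @param cfg configuration list (see [validate_config()], [demo_config()]).
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly. Outputs: `inputs/` (the materialized
#'   inputs), `filtered_*.tsv/.txt`, `proximity_<category>.json/.tsv`,
#'   `clusters.tsv`, `enrichment.tsv`, `enrichment_top.tsv`,
#'   `activity.tsv`, and `manifest.json`.
#' @export
run_all <- function(cfg, out_dir) {
  cfg <- validate_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  in_dir <- file.path(out_dir, "inputs")
  dir.create(in_dir, showWarnings = FALSE)
  gseed <- as.integer(cfg$seed)
  warnings_log <- character(0)
  log_warn <- function(w) {
    warnings_log <<- c(warnings_log, conditionMessage(w))
    invokeRestart("muffleWarning")
  }
  stage_seeds <- list()
  seed_for <- function(stage) {
    s <- derive_seed(gseed, stage)
    stage_seeds[[stage]] <<- s
    s
  }

  # ---- inputs ---------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim <- cfg$simulate
    net <- generate_network(sbm_config(sim$network$block_sizes,
                                       sim$network$p_in, sim$network$p_out,
                                       seed = seed_for("network")))
    sets <- generate_planted_sets(net,
      planted_sets_config(sim$sets$target_block, sim$sets$seed_size,
                          sim$sets$query_size, sim$sets$proximity,
                          seed = seed_for("sets")))
    seed_sets <- list(planted = sets$seed_set)
    query_list <- sets$query_set
    de <- generate_de_table(de_config(sim$de$n_features,
      sim$de$frac_regulated, sim$de$effect_lfc,
      sim$de$n_replicates_per_group, sim$de$sigma, seed = seed_for("de")))
    gmt <- generate_gmt(net, sim$gmt$n_terms, sim$gmt$term_size,
                        sim$gmt$planted_term_block, seed = seed_for("gmt"))
    reg <- if (!is.null(sim$regulons))
      generate_regulons(sim$regulons$n_regulators, sim$regulons$targets_per,
                        sim$regulons$active_fraction,
                        sim$regulons$effect_lfc,
                        seed = seed_for("regulons"),
                        noise_sd = sim$regulons$noise_sd %||% 0.1)
    regulons <- reg$regulons
    activity_de <- reg$de
    write_network(net, file.path(in_dir, "network.sif"), "sif")
    for (nm in names(seed_sets))
      write_gene_list(seed_sets[[nm]],
                      file.path(in_dir, paste0("seeds_", nm, ".txt")))
    write_gene_list(query_list, file.path(in_dir, "query.txt"))
    write_de_table(de, file.path(in_dir, "de_table.tsv"))
    write_gmt(gmt, file.path(in_dir, "gene_sets.gmt"))
    if (!is.null(regulons)) {
      write_regulons(regulons, file.path(in_dir, "regulons.tsv"))
      write_de_table(activity_de, file.path(in_dir, "activity_de.tsv"))
    }
  } else {
    ins <- cfg$inputs
    net <- read_network(ins$network, ins$network_format %||% "sif")
    seed_sets <- lapply(ins$seeds, read_gene_list)
    de <- if (!is.null(ins$query_table)) read_de_table(ins$query_table)
    query_list <- if (!is.null(ins$query_list)) read_gene_list(ins$query_list)
    gmt <- if (!is.null(ins$gmt)) read_gmt(ins$gmt)
    regulons <- if (!is.null(ins$regulons)) read_regulons(ins$regulons)
    activity_de <- de
  }

  # ---- filter ---------------------------------------------------------
  filtered <- NULL
  if (!is.null(de)) {
    spec <- filter_spec(cfg$filter$lfc_cut, cfg$filter$p_cut,
                        cfg$filter$direction, cfg$filter$use_q)
    filtered <- filter_features(de, spec)
    write_tsv(attr(filtered, "table"), file.path(out_dir, "filtered_de.tsv"))
    write_gene_list(filtered, file.path(out_dir, "filtered_de.txt"))
    if (is.null(query_list)) query_list <- as.character(filtered)
  }
  if (is.null(query_list) || !length(query_list))
    stopf("no query list available (provide query_list/query_table or a simulate block)")

  # ---- proximity per seed category -----------------------------------
  prop_cfg <- propagation_config(cfg$propagation$alpha, cfg$propagation$tol,
                                 cfg$propagation$max_iter,
                                 cfg$propagation$normalization)
  prox_results <- list()
  for (nm in names(seed_sets)) {
    prox_cfg <- proximity_config(cfg$proximity$n_random,
      rng_seed = seed_for(paste0("proximity_", nm)),
      exclude_seed_overlap = cfg$proximity$exclude_seed_overlap,
      pvalue_convention = cfg$proximity$pvalue_convention)
    res <- withCallingHandlers(
      run_proximity_test(net, seed_sets[[nm]], query_list, prop_cfg,
                         prox_cfg),
      warning = log_warn)
    prox_results[[nm]] <- res
    write_proximity_result(res,
      file.path(out_dir, paste0("proximity_", nm, ".json")),
      file.path(out_dir, paste0("proximity_", nm, "_random_medians.tsv")))
  }

  # ---- subnetwork, clustering, enrichment ----------------------------
  subnet <- induced_subnetwork(net, query_list)
  clustering <- NULL
  enrichment <- NULL
  if (igraph::vcount(subnet) >= 1L) {
    k <- min(as.integer(cfg$clustering$k), igraph::vcount(subnet))
    clustering <- withCallingHandlers(
      cluster_subnetwork(subnet, k, cfg$clustering$method),
      warning = log_warn)
    write_clustering(clustering, file.path(out_dir, "clusters.tsv"))
    if (!is.null(gmt)) {
      enrichment <- enrich_clusters(clustering, gmt,
                                    universe = igraph::V(net)$name,
                                    top_k = cfg$enrichment$top_k,
                                    fdr_family = cfg$enrichment$fdr_family)
      write_enrichment(enrichment, file.path(out_dir, "enrichment.tsv"))
      write_tsv(enrichment$top, file.path(out_dir, "enrichment_top.tsv"))
    }
  }

  # ---- activity -------------------------------------------------------
  activity <- NULL
  if (!is.null(regulons) && !is.null(activity_de)) {
    activity <- permutation_activity(activity_de, regulons,
      n_perm = cfg$activity$n_perm,
      rng_seed = seed_for("activity"),
      min_targets = cfg$activity$min_targets)
    write_activity(activity, file.path(out_dir, "activity.tsv"))
  } else {
    message("activity stage skipped: no regulons supplied")
  }

  # ---- manifest -------------------------------------------------------
  input_files <- sort(list.files(in_dir, full.names = TRUE))
  checksums <- if (length(input_files)) {
    md5 <- tools::md5sum(input_files)
    stats::setNames(as.character(md5), basename(names(md5)))
  } else NULL
  manifest <- list(
    package = "propnet",
    package_version = as.character(utils::packageVersion("propnet")),
    config = cfg,
    global_seed = gseed,
    stage_seeds = stage_seeds,
    input_checksums = as.list(checksums),
    proximity = lapply(prox_results, function(r)
      r[c("observed_median", "empirical_p", "n_query_used", "n_random",
          "convention", "converged")]),
    n_subnetwork_nodes = igraph::vcount(subnet),
    n_subnetwork_edges = igraph::ecount(subnet),
    warnings = warnings_log
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
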