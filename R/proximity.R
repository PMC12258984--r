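# Median-heat proximity of a query gene set to a seed set, with an
# empirical p-value against size-matched random gene sets drawn from the
# network. One propagation is run per test; the observed and all random
# medians are read off the same heat vector.

#' Proximity-test configuration
#'
#' @param n_random number of size-matched random sets (the study design
#'   this mirrors uses 1000).
#' @param rng_seed integer seed for the random-set sampler.
#' @param exclude_seed_overlap if `TRUE`, seed genes are removed from the
#'   query statistic and from the sampling universe. Off by default: the
#'   seed/query overlap is usually biologically meaningful.
#' @param pvalue_convention `"plus_one"` (default; p = (1 + #\{r >= obs\}) /
#'   (N + 1), never zero) or `"rank_over_n"` (rank of the observed value in
#'   the descending-sorted pooled list divided by N, ties placed before the
#'   observed value).
#' @return a validated `proximity_config` list.
#' @export
proximity_config <- function(n_random = 1000L, rng_seed = 1L,
                             exclude_seed_overlap = FALSE,
                             pvalue_convention = c("plus_one", "rank_over_n")) {
  pvalue_convention <- match.arg(pvalue_convention)
  structure(list(n_random = check_count(n_random, "n_random"),
                 rng_seed = check_count(rng_seed, "rng_seed", min = 0L),
                 exclude_seed_overlap = isTRUE(exclude_seed_overlap),
                 pvalue_convention = pvalue_convention),
            class = "proximity_config")
}

#' Median heat over a query gene set
#'
#' @param heat named heat vector from [propagate()].
#' @param query nonempty character vector of query symbols.
#' @param exclude optional symbols removed from the query before taking
#'   the median.
#' @return the median heat, with attributes `n_used` and `n_unmapped`.
#' @export
median_heat <- function(heat, query, exclude = NULL) {
  query <- unique(normalize_symbols(query))
  if (!length(query)) stopf("`query` must be nonempty")
  if (!is.null(exclude)) query <- setdiff(query, normalize_symbols(exclude))
  mapped <- intersect(query, names(heat))
  if (!length(mapped))
    stopf("no query gene maps into the heat vector (after exclusions)")
  structure(stats::median(as.numeric(heat[mapped])),
            n_used = length(mapped),
            n_unmapped = length(setdiff(query, mapped)))
}

#' Size-matched random gene sets
#'
#' Draws `n_random` sets of the given size uniformly without replacement
#' from the universe; reproducible under `rng_seed`.
#'
#' @param universe character vector of symbols to sample from.
#' @param size set size (must not exceed the universe).
#' @param n_random number of sets.
#' @param rng_seed integer seed.
#' @return list of `n_random` character vectors.
#' @export
sample_size_matched <- function(universe, size, n_random, rng_seed) {
  universe <- unique(normalize_symbols(universe))
  size <- check_count(size, "size")
  n_random <- check_count(n_random, "n_random")
  if (size > length(universe))
    stopf("requested set size %d exceeds universe size %d", size,
          length(universe))
  local_seed(rng_seed,
             lapply(seq_len(n_random), function(i) sample(universe, size)))
}

#' Empirical p-value of an observed statistic against a null sample
#'
#' `plus_one`: p = (1 + #\{r >= observed\}) / (N + 1); the standard
#' permutation estimator, bounded below by 1/(N + 1). `rank_over_n`: the
#' position of the observed value in the descending-sorted pooled list
#' divided by N, with tied null values placed before the observed value
#' (conservative).
#'
#' @param observed observed statistic (finite).
#' @param randoms nonempty numeric vector of null statistics (finite).
#' @param convention `"plus_one"` or `"rank_over_n"`.
#' @return empirical p-value in (0, 1].
#' @export
empirical_pvalue <- function(observed, randoms,
                             convention = c("plus_one", "rank_over_n")) {
  convention <- match.arg(convention)
  if (!length(randoms)) stopf("`randoms` must be nonempty")
  if (!is.finite(observed) || any(!is.finite(randoms)))
    stopf("non-finite statistic passed to empirical_pvalue()")
  n_ge <- sum(randoms >= observed)
  if (convention == "plus_one")
    (1 + n_ge) / (length(randoms) + 1)
  else
    (n_ge + 1) / length(randoms)
}

#' Run a full network-proximity test
#'
#' Propagates heat from the seed set (on the largest connected component;
#' off-component genes keep heat 0 but remain in the statistic), computes
#' the median heat of the query set, and compares it with the medians of
#' `n_random` size-matched random gene sets drawn from the full node set,
#' all evaluated on the single shared heat vector.
#'
#' @param net an `igraph` gene network.
#' @param seed_set character vector of seed symbols (initiate diffusion).
#' @param query_set character vector of query symbols (tested for
#'   proximity).
#' @param prop_cfg a [propagation_config()].
#' @param prox_cfg a [proximity_config()].
#' @return object of class `proximity_result`: observed median, the vector
#'   of random medians, the empirical p-value, mapping counts, and the
#'   propagation provenance.
#' @export
run_proximity_test <- function(net, seed_set, query_set,
                               prop_cfg = propagation_config(),
                               prox_cfg = proximity_config()) {
  stopifnot(inherits(prox_cfg, "proximity_config"))
  seed_set <- unique(normalize_symbols(seed_set))
  query_set <- unique(normalize_symbols(query_set))
  nodes <- igraph::V(net)$name

  lcc <- largest_connected_component(net)
  f0 <- make_seed_vector(lcc, seed_set)
  h <- propagate(lcc, f0, prop_cfg)
  heat <- stats::setNames(numeric(length(nodes)), nodes)
  heat[names(h)] <- as.numeric(h)

  exclude <- if (prox_cfg$exclude_seed_overlap) seed_set else NULL
  obs <- median_heat(heat, query_set, exclude = exclude)
  size <- attr(obs, "n_used")
  universe <- if (prox_cfg$exclude_seed_overlap) setdiff(nodes, seed_set)
              else nodes
  randoms <- sample_size_matched(universe, size, prox_cfg$n_random,
                                 prox_cfg$rng_seed)
  random_medians <- vapply(randoms, function(s)
    stats::median(as.numeric(heat[s])), numeric(1))
  p <- empirical_pvalue(as.numeric(obs), random_medians,
                        prox_cfg$pvalue_convention)

  structure(list(
    observed_median = as.numeric(obs),
    random_medians = random_medians,
    empirical_p = p,
    n_query_mapped = length(intersect(query_set, nodes)),
    n_query_used = attr(obs, "n_used"),
    n_random = prox_cfg$n_random,
    convention = prox_cfg$pvalue_convention,
    exclude_seed_overlap = prox_cfg$exclude_seed_overlap,
    rng_seed = prox_cfg$rng_seed,
    alpha = prop_cfg$alpha,
    normalization = prop_cfg$normalization,
    converged = attr(h, "converged"),
    iterations = attr(h, "iterations"),
    n_nodes = length(nodes),
    n_seed_mapped = sum(f0 > 0)
  ), class = "proximity_result")
}

#' @export
print.proximity_result <- function(x, ...) {
  cat(sprintf(paste0(
    "Network proximity test\n",
    "  nodes: %d | seeds mapped: %d | query used: %d\n",
    "  observed median heat: %.6g\n",
    "  random medians (n = %d): median %.6g\n",
    "  empirical p (%s): %.4g%s\n"),
    x$n_nodes, x$n_seed_mapped, x$n_query_used,
    x$observed_median, x$n_random, stats::median(x$random_medians),
    x$convention, x$empirical_p,
    if (isTRUE(x$converged)) "" else "  [propagation NOT converged]"))
  invisible(x)
}

#' Serialize a proximity result
#'
#' Writes the scalar summary as JSON and the random medians as TSV.
#'
#' @param result a `proximity_result`.
#' @param json_path JSON output path.
#' @param tsv_path optional TSV path for the random medians.
#' @export
write_proximity_result <- function(result, json_path, tsv_path = NULL) {
  scalars <- result[setdiff(names(result), "random_medians")]
  jsonlite::write_json(scalars, json_path, auto_unbox = TRUE, pretty = TRUE,
                       digits = NA)
  if (!is.null(tsv_path)) {
    df <- data.frame(replicate = seq_along(result$random_medians),
                     median_heat = result$random_medians)
    utils::write.table(df, tsv_path, sep = "\t", quote = FALSE,
                       row.names = FALSE)
  }
  invisible(json_path)
}
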