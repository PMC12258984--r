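# Synthetic-data generators. Every generator is a pure function of its
# configuration (seed included): networks are stochastic block models with
# a planted module standing in for a disease pathway neighbourhood; seed
# and query gene sets are planted at a tunable proximity to that module;
# differential-statistics tables come from a two-group normal model with a
# Welch t-test; gene-set collections and regulons carry planted structure
# with retained ground truth.

#' Stochastic-block-model network configuration
#'
#' @param block_sizes positive integer vector, nodes per module.
#' @param p_in within-module edge probability.
#' @param p_out between-module edge probability (a warning is raised when
#'   `p_out > p_in`, which removes the planted modularity).
#' @param seed integer RNG seed.
#' @return a validated `sbm_config` list.
#' @export
sbm_config <- function(block_sizes, p_in, p_out, seed = 1L) {
  if (!length(block_sizes) || any(block_sizes < 1) ||
      any(block_sizes != round(block_sizes)))
    stopf("`block_sizes` must be positive integers")
  if (sum(block_sizes) < 2) stopf("the network must have >= 2 nodes")
  p_in <- check_prob(p_in, "p_in")
  p_out <- check_prob(p_out, "p_out")
  if (p_out > p_in)
    warnf("p_out (%g) > p_in (%g): blocks will not be assortative modules",
          p_out, p_in)
  structure(list(block_sizes = as.integer(block_sizes), p_in = p_in,
                 p_out = p_out, seed = check_count(seed, "seed", min = 0L)),
            class = "sbm_config")
}

#' Generate a modular synthetic gene network
#'
#' Samples a stochastic block model, names nodes with zero-padded synthetic
#' gene symbols ("G0001", ...), and records block membership in the vertex
#' attribute `block`.
#'
#' @param cfg an [sbm_config()].
#' @return a simple undirected `igraph`.
#' @export
generate_network <- function(cfg) {
  stopifnot(inherits(cfg, "sbm_config"))
  bs <- cfg$block_sizes
  n <- sum(bs)
  P <- matrix(cfg$p_out, length(bs), length(bs))
  diag(P) <- cfg$p_in
  g <- local_seed(cfg$seed,
                  igraph::sample_sbm(n, pref.matrix = P, block.sizes = bs))
  g <- igraph::simplify(g)
  width <- max(4L, nchar(as.character(n)))
  igraph::V(g)$name <- sprintf("G%0*d", width, seq_len(n))
  igraph::V(g)$block <- rep(seq_along(bs), bs)
  g
}

#' Planted seed/query set configuration
#'
#' @param target_block index of the module the sets are planted in.
#' @param seed_size size of the seed set (drawn entirely from the target
#'   block).
#' @param query_size size of the query set.
#' @param proximity fraction of query genes drawn from the target block;
#'   the remainder is drawn uniformly from the other blocks.
#' @param seed integer RNG seed.
#' @return a validated `planted_sets_config` list.
#' @export
planted_sets_config <- function(target_block, seed_size, query_size,
                                proximity, seed = 1L) {
  structure(list(target_block = check_count(target_block, "target_block"),
                 seed_size = check_count(seed_size, "seed_size"),
                 query_size = check_count(query_size, "query_size"),
                 proximity = check_prob(proximity, "proximity"),
                 seed = check_count(seed, "seed", min = 0L)),
            class = "planted_sets_config")
}

#' Plant seed and query gene sets on a modular network
#'
#' The seed set is sampled from the target block; the query set has exactly
#' `round(proximity * query_size)` members in the target block and the rest
#' uniform over the remaining blocks. Both are sampled without replacement;
#' seed/query overlap is allowed (and meaningful).
#'
#' @param net a network from [generate_network()] (must carry `block`
#'   metadata).
#' @param cfg a [planted_sets_config()].
#' @return list with sorted character vectors `seed_set` and `query_set`.
#' @export
generate_planted_sets <- function(net, cfg) {
  stopifnot(inherits(cfg, "planted_sets_config"))
  blocks <- igraph::V(net)$block
  if (is.null(blocks)) stopf("network carries no `block` vertex metadata")
  nodes <- igraph::V(net)$name
  inb <- nodes[blocks == cfg$target_block]
  outb <- nodes[blocks != cfg$target_block]
  if (!length(inb)) stopf("target_block %d has no nodes", cfg$target_block)
  n_in <- round(cfg$proximity * cfg$query_size)
  if (cfg$seed_size > length(inb))
    stopf("seed_size %d exceeds the target block (%d nodes)",
          cfg$seed_size, length(inb))
  if (n_in > length(inb))
    stopf("proximity * query_size (%d) exceeds the target block (%d nodes)",
          n_in, length(inb))
  if (cfg$query_size - n_in > length(outb))
    stopf("query_size - in-block part (%d) exceeds the %d off-block nodes",
          cfg$query_size - n_in, length(outb))
  local_seed(cfg$seed, {
    seed_set <- sort(sample(inb, cfg$seed_size))
    query_set <- sort(c(sample(inb, n_in),
                        if (cfg$query_size > n_in)
                          sample(outb, cfg$query_size - n_in)))
    list(seed_set = seed_set, query_set = query_set)
  })
}

#' Differential-expression surrogate configuration
#'
#' @param n_features number of features (genes/proteins/phosphosites).
#' @param frac_regulated fraction with a planted mean shift.
#' @param effect_lfc planted mean log2 fold change.
#' @param n_replicates_per_group replicates per group (>= 2, Welch t-test).
#' @param sigma within-group standard deviation on the log scale.
#' @param seed integer RNG seed.
#' @return a validated `de_config` list.
#' @export
de_config <- function(n_features, frac_regulated, effect_lfc,
                      n_replicates_per_group, sigma, seed = 1L) {
  if (!is.numeric(sigma) || length(sigma) != 1L || !is.finite(sigma) ||
      sigma <= 0)
    stopf("`sigma` must be a single positive number")
  structure(list(
    n_features = check_count(n_features, "n_features"),
    frac_regulated = check_prob(frac_regulated, "frac_regulated"),
    effect_lfc = as.numeric(effect_lfc),
    n_replicates_per_group = check_count(n_replicates_per_group,
                                         "n_replicates_per_group", min = 2L),
    sigma = as.numeric(sigma),
    seed = check_count(seed, "seed", min = 0L)),
    class = "de_config")
}

#' Generate a synthetic differential-statistics table
#'
#' Per feature, two groups of normal log-scale replicates are simulated;
#' regulated features get a mean shift of `effect_lfc` in group 2. The
#' table reports `log2fc` (difference of group means), `pvalue` (two-sided
#' Welch t-test), and the ground-truth `regulated` flag.
#'
#' @param cfg a [de_config()].
#' @return a `data.frame` with columns `feature_id`, `log2fc`, `pvalue`,
#'   `regulated`.
#' @export
generate_de_table <- function(cfg) {
  stopifnot(inherits(cfg, "de_config"))
  n <- cfg$n_features
  nrep <- cfg$n_replicates_per_group
  local_seed(cfg$seed, {
    regulated <- logical(n)
    n_reg <- round(cfg$frac_regulated * n)
    if (n_reg > 0) regulated[sample.int(n, n_reg)] <- TRUE
    g1 <- matrix(stats::rnorm(n * nrep, 0, cfg$sigma), nrow = n)
    g2 <- matrix(stats::rnorm(n * nrep, ifelse(regulated, cfg$effect_lfc, 0),
                              cfg$sigma), nrow = n)
    log2fc <- rowMeans(g2) - rowMeans(g1)
    pvalue <- vapply(seq_len(n), function(i)
      stats::t.test(g2[i, ], g1[i, ], var.equal = FALSE)$p.value, numeric(1))
    data.frame(feature_id = sprintf("F%0*d", max(5L, nchar(n)), seq_len(n)),
               log2fc = log2fc, pvalue = pvalue, regulated = regulated)
  })
}

#' Generate a synthetic gene-set collection
#'
#' `n_terms` random terms drawn uniformly from the network nodes, plus one
#' planted term (`"PLANTED_TERM"`) drawn entirely from the given block.
#'
#' @param net a network from [generate_network()].
#' @param n_terms number of random terms.
#' @param term_size genes per term (>= 1, at most the node count and the
#'   planted block size).
#' @param planted_term_block block index the planted term is drawn from.
#' @param seed integer RNG seed.
#' @return a [gene_set_collection] of `n_terms + 1` terms.
#' @export
generate_gmt <- function(net, n_terms, term_size, planted_term_block,
                         seed = 1L) {
  n_terms <- check_count(n_terms, "n_terms", min = 0L)
  term_size <- check_count(term_size, "term_size")
  nodes <- igraph::V(net)$name
  blocks <- igraph::V(net)$block
  if (is.null(blocks)) stopf("network carries no `block` vertex metadata")
  if (term_size > length(nodes))
    stopf("term_size %d exceeds the node count %d", term_size, length(nodes))
  inb <- nodes[blocks == planted_term_block]
  if (term_size > length(inb))
    stopf("term_size %d exceeds the planted block (%d nodes)", term_size,
          length(inb))
  local_seed(seed, {
    sets <- lapply(seq_len(n_terms), function(i) sort(sample(nodes, term_size)))
    names(sets) <- sprintf("RANDOM_TERM_%02d", seq_len(n_terms))
    sets[["PLANTED_TERM"]] <- sort(sample(inb, term_size))
    gene_set_collection(sets,
                        c(rep("random synthetic term", n_terms),
                          sprintf("planted term from block %d",
                                  planted_term_block)))
  })
}

#' Generate synthetic regulons with a paired DE table
#'
#' Each regulator gets `targets_per` distinct targets with signed weights.
#' For "active" regulators, the paired DE table plants target
#' `log2fc = weight * effect_lfc + noise`; all other features are pure
#' noise. P-values are two-sided normal tails of `log2fc / noise_sd`
#' (uniform under the null). Ground-truth activity labels are retained.
#'
#' @param n_regulators number of regulators (>= 1).
#' @param targets_per targets per regulator (>= 3).
#' @param active_fraction fraction of regulators with planted activity.
#' @param effect_lfc planted effect size on active targets.
#' @param seed integer RNG seed.
#' @param noise_sd standard deviation of the target-level noise.
#' @param prob_repression probability that a target weight is -1 rather
#'   than +1. The default 0.5 (balanced activated/repressed targets) keeps
#'   the global fold-change distribution centered, so the gene-label
#'   permutation null is unbiased for inactive regulators; skewed regulons
#'   shift it.
#' @param n_null_features extra unregulated features appended to the DE
#'   table.
#' @return list with `regulons` (data.frame regulator/target/weight), `de`
#'   (paired DE table with a `regulated` truth column) and
#'   `active_regulators` (character vector).
#' @export
generate_regulons <- function(n_regulators, targets_per, active_fraction,
                              effect_lfc, seed = 1L, noise_sd = 0.1,
                              prob_repression = 0.5, n_null_features = 0L) {
  n_regulators <- check_count(n_regulators, "n_regulators")
  targets_per <- check_count(targets_per, "targets_per", min = 3L)
  active_fraction <- check_prob(active_fraction, "active_fraction")
  prob_repression <- check_prob(prob_repression, "prob_repression")
  n_null_features <- check_count(n_null_features, "n_null_features", min = 0L)
  if (noise_sd <= 0) stopf("`noise_sd` must be positive")
  n_targets <- n_regulators * targets_per
  regs <- sprintf("R%02d", seq_len(n_regulators))
  feats <- sprintf("T%0*d", max(4L, nchar(n_targets)), seq_len(n_targets))
  local_seed(seed, {
    n_active <- round(active_fraction * n_regulators)
    active <- sort(if (n_active > 0) sample(regs, n_active) else character(0))
    regulons <- data.frame(
      regulator = rep(regs, each = targets_per),
      target = feats,
      weight = sample(c(1, -1), n_targets, replace = TRUE,
                      prob = c(1 - prob_repression, prob_repression)))
    is_active_target <- regulons$regulator %in% active
    lfc <- stats::rnorm(n_targets, 0, noise_sd) +
      ifelse(is_active_target, regulons$weight * effect_lfc, 0)
    if (n_null_features > 0) {
      null_feats <- sprintf("N%0*d", max(4L, nchar(n_null_features)),
                            seq_len(n_null_features))
      lfc <- c(lfc, stats::rnorm(n_null_features, 0, noise_sd))
      ids <- c(feats, null_feats)
      regulated <- c(is_active_target, rep(FALSE, n_null_features))
    } else {
      ids <- feats
      regulated <- is_active_target
    }
    de <- data.frame(feature_id = ids, log2fc = lfc,
                     pvalue = pmin(1, 2 * stats::pnorm(-abs(lfc) / noise_sd)),
                     regulated = regulated)
    list(regulons = regulons, de = de, active_regulators = active)
  })
}

#' Read / write a regulon network as 3-column TSV
#'
#' Columns: `regulator`, `target`, `weight`. Duplicate (regulator, target)
#' pairs or zero/non-finite weights are rejected.
#'
#' @param path file path.
#' @return validated `data.frame`.
#' @export
read_regulons <- function(path) {
  if (!file.exists(path)) stopf("regulon file not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_regulons(df)
}

#' @rdname read_regulons
#' @param regulons regulon `data.frame`.
#' @export
write_regulons <- function(regulons, path) {
  regulons <- validate_regulons(regulons)
  utils::write.table(regulons, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_regulons
#' @export
validate_regulons <- function(regulons) {
  req <- c("regulator", "target", "weight")
  missing <- setdiff(req, names(regulons))
  if (length(missing))
    stopf("regulon table is missing column(s): %s",
          paste(missing, collapse = ", "))
  if (!nrow(regulons)) stopf("regulon table is empty")
  regulons$regulator <- normalize_symbols(regulons$regulator)
  regulons$target <- normalize_symbols(regulons$target)
  if (anyDuplicated(regulons[, c("regulator", "target")]))
    stopf("duplicate (regulator, target) pair(s)")
  if (any(!is.finite(regulons$weight)) || any(regulons$weight == 0))
    stopf("regulon weights must be finite and nonzero")
  regulons
}
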