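# Regulator (TF/kinase) activity inference from target-level fold changes:
# a weighted-mean statistic with a gene-label permutation z-score. This is
# a deliberately transparent scorer for the activity-ranking stage; it is
# not a motif-based phosphosite scorer and makes no attempt to reproduce
# multi-method consensus pipelines.

#' Weighted-mean activity statistic for one regulon
#'
#' m = sum(w_i * x_i) / sum(|w_i|) over the regulon targets mapped into the
#' statistics table, with x_i the target log2 fold change. Invariant to
#' positive rescaling of the weights; negating all fold changes negates m.
#'
#' @param stats DE-statistics `data.frame` (see [read_de_table()]).
#' @param targets character vector of target symbols.
#' @param weights signed numeric weights, parallel to `targets`.
#' @param min_targets minimum mapped targets required (default 3); below
#'   this `NA` is returned.
#' @return the statistic, with the mapped-target count in attribute
#'   `"n_mapped"`.
#' @export
weighted_mean_score <- function(stats, targets, weights, min_targets = 3L) {
  stats <- validate_de_table(stats)
  if (length(targets) != length(weights))
    stopf("`targets` and `weights` must have equal length")
  idx <- match(normalize_symbols(targets), stats$feature_id)
  ok <- !is.na(idx)
  if (sum(ok) < min_targets)
    return(structure(NA_real_, n_mapped = sum(ok)))
  w <- as.numeric(weights[ok])
  x <- stats$log2fc[idx[ok]]
  structure(sum(w * x) / sum(abs(w)), n_mapped = sum(ok))
}

#' Permutation z-scores for regulator activity
#'
#' For each regulator, the observed weighted-mean statistic is compared
#' with its distribution under `n_perm` permutations of the log2FC values
#' across all features (regulon size and weight structure preserved):
#' z = (m_obs - mean(m_perm)) / sd(m_perm), with an empirical p-value by
#' the plus-one rule. A zero permutation sd yields z = 0 with a
#' `degenerate` flag. Regulators with fewer than `min_targets` mapped
#' targets are skipped and reported in the `"skipped"` attribute.
#'
#' @param stats DE-statistics `data.frame`.
#' @param regulons regulon `data.frame` (regulator, target, weight).
#' @param n_perm number of permutations (>= 100 recommended).
#' @param rng_seed integer seed.
#' @param min_targets minimum mapped targets per regulator.
#' @return `data.frame` (one row per scored regulator, sorted by
#'   descending z, ties by regulator symbol) with columns `regulator`,
#'   `n_targets_mapped`, `weighted_mean`, `z`, `empirical_p`, `degenerate`.
#' @export
permutation_activity <- function(stats, regulons, n_perm = 1000L,
                                 rng_seed = 1L, min_targets = 3L) {
  stats <- validate_de_table(stats)
  regulons <- validate_regulons(regulons)
  n_perm <- check_count(n_perm, "n_perm")
  x <- stats::setNames(stats$log2fc, stats$feature_id)
  n_feat <- length(x)
  perm_mat <- local_seed(rng_seed,
    vapply(seq_len(n_perm), function(i) x[sample.int(n_feat)],
           numeric(n_feat)))
  by_reg <- split(regulons[, c("target", "weight")], regulons$regulator)
  skipped <- character(0)
  rows <- list()
  for (reg in names(by_reg)) {
    r <- by_reg[[reg]]
    idx <- match(r$target, names(x))
    ok <- !is.na(idx)
    if (sum(ok) < min_targets) {
      skipped <- c(skipped, reg)
      next
    }
    w <- r$weight[ok]
    i <- idx[ok]
    denom <- sum(abs(w))
    m_obs <- sum(w * x[i]) / denom
    m_perm <- as.numeric(w %*% perm_mat[i, , drop = FALSE]) / denom
    s <- stats::sd(m_perm)
    degenerate <- !is.finite(s) || s == 0
    z <- if (degenerate) 0 else (m_obs - mean(m_perm)) / s
    rows[[reg]] <- data.frame(
      regulator = reg, n_targets_mapped = sum(ok), weighted_mean = m_obs,
      z = z, empirical_p = (1 + sum(m_perm >= m_obs)) / (n_perm + 1),
      degenerate = degenerate)
  }
  out <- if (length(rows)) do.call(rbind, rows)
         else data.frame(regulator = character(0),
                         n_targets_mapped = integer(0),
                         weighted_mean = numeric(0), z = numeric(0),
                         empirical_p = numeric(0), degenerate = logical(0))
  out <- out[order(-out$z, out$regulator), , drop = FALSE]
  rownames(out) <- NULL
  structure(out, skipped = skipped)
}

#' Rank regulators by activity z-score
#'
#' @param scores a [permutation_activity()] table.
#' @param top_k how many regulators to report on each side.
#' @return list with `activated` (top `top_k` by descending z) and
#'   `deactivated` (top `top_k` by ascending z) character vectors, plus the
#'   full `table` sorted by descending z (ties by symbol).
#' @export
rank_regulators <- function(scores, top_k = 5L) {
  top_k <- check_count(top_k, "top_k")
  if (!nrow(scores))
    return(list(activated = character(0), deactivated = character(0),
                table = scores))
  desc <- scores[order(-scores$z, scores$regulator), , drop = FALSE]
  asc <- scores[order(scores$z, scores$regulator), , drop = FALSE]
  list(activated = utils::head(desc$regulator, top_k),
       deactivated = utils::head(asc$regulator, top_k),
       table = desc)
}

#' Write an activity table as TSV (sorted by z)
#'
#' @param scores a [permutation_activity()] table.
#' @param path output path.
#' @export
write_activity <- function(scores, path) {
  utils::write.table(scores, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
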