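# Differential-statistics tables, threshold filters, and the set algebra
# (intersection, union, size matching) used to define omics gene lists.

#' Read / write a differential-statistics table
#'
#' TSV with at least the columns `feature_id`, `log2fc`, `pvalue`; extra
#' columns are preserved. Feature ids are normalized, must be unique;
#' p-values must lie in (0, 1] and log2 fold changes must be finite.
#'
#' @param path file path.
#' @return a validated `data.frame`.
#' @export
read_de_table <- function(path) {
  if (!file.exists(path)) stopf("DE table not found: %s", path)
  df <- utils::read.delim(path, sep = "\t", stringsAsFactors = FALSE)
  validate_de_table(df)
}

#' @rdname read_de_table
#' @param table a DE-statistics `data.frame`.
#' @export
write_de_table <- function(table, path) {
  table <- validate_de_table(table)
  utils::write.table(table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname read_de_table
#' @export
validate_de_table <- function(table) {
  req <- c("feature_id", "log2fc", "pvalue")
  missing <- setdiff(req, names(table))
  if (length(missing))
    stopf("DE table is missing required column(s): %s",
          paste(missing, collapse = ", "))
  table$feature_id <- normalize_symbols(table$feature_id)
  if (anyDuplicated(table$feature_id))
    stopf("duplicate feature_id(s) in DE table")
  if (any(!is.finite(table$log2fc)))
    stopf("non-finite log2fc value(s) in DE table")
  if (any(!is.finite(table$pvalue)) || any(table$pvalue <= 0) ||
      any(table$pvalue > 1))
    stopf("p-values must lie in (0, 1]")
  table
}

#' Threshold filter specification
#'
#' Cutoffs are applied as strict inequalities, exactly as printed in the
#' usual volcano-plot captions: |log2FC| > `lfc_cut` and p < `p_cut`;
#' boundary rows are excluded. The p-value filtered on is the raw p by
#' default (`use_q = FALSE`); set `use_q = TRUE` to filter on BH q-values
#' computed over the whole table instead.
#'
#' @param lfc_cut nonnegative log2 fold-change cutoff (e.g. 2 for RNA,
#'   1 for protein/phosphosite lists).
#' @param p_cut p-value cutoff in (0, 1].
#' @param direction `"up"`, `"down"` or `"both"`.
#' @param use_q filter on BH-adjusted values instead of raw p.
#' @return a validated `filter_spec` list.
#' @export
filter_spec <- function(lfc_cut = 2, p_cut = 0.05,
                        direction = c("both", "up", "down"),
                        use_q = FALSE) {
  direction <- match.arg(direction)
  if (!is.numeric(lfc_cut) || length(lfc_cut) != 1L || !is.finite(lfc_cut) ||
      lfc_cut < 0)
    stopf("`lfc_cut` must be a single nonnegative number")
  p_cut <- check_prob(p_cut, "p_cut", open_lo = TRUE)
  structure(list(lfc_cut = as.numeric(lfc_cut), p_cut = p_cut,
                 direction = direction, use_q = isTRUE(use_q)),
            class = "filter_spec")
}

#' Apply a threshold filter to a DE table
#'
#' @param table DE-statistics `data.frame` (see [read_de_table()]).
#' @param spec a [filter_spec()].
#' @return character vector of retained feature ids sorted by descending
#'   |log2FC| (ties by id), with the retained rows in the `"table"`
#'   attribute.
#' @export
filter_features <- function(table, spec = filter_spec()) {
  stopifnot(inherits(spec, "filter_spec"))
  table <- validate_de_table(table)
  if (!nrow(table)) stopf("DE table is empty")
  pv <- if (spec$use_q) bh_fdr(table$pvalue) else table$pvalue
  keep <- pv < spec$p_cut & switch(spec$direction,
    up = table$log2fc > spec$lfc_cut,
    down = table$log2fc < -spec$lfc_cut,
    both = abs(table$log2fc) > spec$lfc_cut)
  out <- table[keep, , drop = FALSE]
  out <- out[order(-abs(out$log2fc), out$feature_id), , drop = FALSE]
  structure(out$feature_id, table = out)
}

#' Intersect two gene lists after symbol normalization
#'
#' @param a,b character vectors of symbols.
#' @return sorted character vector of the intersection, with the overlap
#'   size in the `"n"` attribute.
#' @export
intersect_lists <- function(a, b) {
  out <- sort(intersect(unique(normalize_symbols(a)),
                        unique(normalize_symbols(b))))
  structure(out, n = length(out))
}

#' Union of gene lists with per-source membership
#'
#' @param lists list of character vectors (optionally named by source).
#' @return sorted character vector of the union; the `"membership"`
#'   attribute holds a logical data.frame (gene x source).
#' @export
union_lists <- function(lists) {
  if (!length(lists)) return(structure(character(0),
                                       membership = data.frame()))
  lists <- lapply(lists, function(x) unique(normalize_symbols(x)))
  if (is.null(names(lists)) || any(!nzchar(names(lists))))
    names(lists) <- paste0("source", seq_along(lists))
  u <- sort(unique(unlist(lists, use.names = FALSE)))
  membership <- as.data.frame(lapply(lists, function(x) u %in% x),
                              row.names = u, optional = TRUE)
  structure(u, membership = membership)
}

#' Top-n size matching of a DE table
#'
#' Selects the top `n` features by descending |log2FC| (`"abs_lfc"`) or
#' ascending p-value (`"pvalue"`); ties are broken by ascending feature id.
#'
#' @param table DE-statistics `data.frame`.
#' @param n number of features to keep (must not exceed the table).
#' @param ranking_key `"abs_lfc"` or `"pvalue"`.
#' @return character vector of `n` feature ids in ranking order.
#' @export
size_match <- function(table, n, ranking_key = c("abs_lfc", "pvalue")) {
  ranking_key <- match.arg(ranking_key)
  table <- validate_de_table(table)
  n <- check_count(n, "n")
  if (n > nrow(table))
    stopf("n = %d exceeds the %d available feature(s)", n, nrow(table))
  ord <- if (ranking_key == "abs_lfc")
    order(-abs(table$log2fc), table$feature_id)
  else order(table$pvalue, table$feature_id)
  table$feature_id[ord][seq_len(n)]
}

#' Analytic power of a fold-change + p-value threshold filter
#'
#' For the two-group normal model behind [generate_de_table()] (replicate
#' means shifted by `effect_lfc`, within-group sd `sigma`, Welch t-test),
#' computes P(|log2FC| > lfc_cut and p < p_cut) by deterministic numerical
#' integration over the two group sample variances (chi-square quantile
#' midpoint grid). Given the variances the mean difference is independent
#' and normal, so the joint pass probability has a closed form per grid
#' node.
#'
#' @param effect_lfc true mean log2 fold change.
#' @param sigma within-group standard deviation on the log scale.
#' @param n_replicates replicates per group (>= 2).
#' @param lfc_cut,p_cut filter cutoffs (strict inequalities).
#' @param direction `"both"` or `"up"`.
#' @param grid_points quadrature nodes per variance axis.
#' @return scalar power in \[0, 1\].
#' @export
filter_power <- function(effect_lfc, sigma, n_replicates, lfc_cut = 2,
                         p_cut = 0.05, direction = c("both", "up"),
                         grid_points = 160L) {
  direction <- match.arg(direction)
  n <- check_count(n_replicates, "n_replicates", min = 2L)
  df <- n - 1L
  u <- (seq_len(grid_points) - 0.5) / grid_points
  s2 <- sigma^2 * stats::qchisq(u, df) / df      # sample-variance nodes
  g <- expand.grid(s1 = s2, s2 = s2)
  se2 <- (g$s1 + g$s2) / n
  se <- sqrt(se2)
  df_w <- se2^2 / ((g$s1 / n)^2 / df + (g$s2 / n)^2 / df)
  thr <- pmax(lfc_cut, stats::qt(1 - p_cut / 2, df_w) * se)
  sdd <- sigma * sqrt(2 / n)                      # sd of the mean difference
  pass <- stats::pnorm((effect_lfc - thr) / sdd)
  if (direction == "both")
    pass <- pass + stats::pnorm((-effect_lfc - thr) / sdd)
  mean(pass)
}
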