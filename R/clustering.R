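# Subnetwork clustering and per-cluster overrepresentation analysis.
# Clustering is agglomerative average linkage on shortest-path hop
# distances; disconnected node pairs are pushed apart by a constant larger
# than the diameter of the largest component, so components separate
# before any intra-component split.

#' Hierarchically cluster a subnetwork into k subclusters
#'
#' @param subnet a nonempty `igraph` subnetwork.
#' @param k number of clusters (1..node count). A warning is raised when
#'   `k` is below the number of connected components, which forces distinct
#'   components into one cluster.
#' @param method `"average_linkage"` (default; hop-distance average-linkage
#'   hierarchical clustering) or `"greedy_modularity"` (robustness
#'   alternative via igraph's fast-greedy community merges).
#' @return object of class `subnetwork_clustering` with elements
#'   `membership` (named integer vector, cluster ids contiguous from 1),
#'   `k`, `method` and, for the hierarchical method, the `hclust` object in
#'   `linkage`.
#' @export
cluster_subnetwork <- function(subnet, k,
                               method = c("average_linkage",
                                          "greedy_modularity")) {
  method <- match.arg(method)
  n <- igraph::vcount(subnet)
  if (n == 0L) stopf("empty subnetwork")
  k <- check_count(k, "k")
  if (k > n) stopf("k = %d exceeds the node count %d", k, n)
  ncomp <- igraph::components(subnet)$no
  if (k < ncomp)
    warnf("k = %d is below the number of connected components (%d); components will be merged",
          k, ncomp)
  if (n == 1L) {
    mem <- stats::setNames(1L, igraph::V(subnet)$name)
    return(structure(list(membership = mem, k = 1L, method = method,
                          linkage = NULL),
                     class = "subnetwork_clustering"))
  }
  if (method == "average_linkage") {
    D <- igraph::distances(subnet)
    if (any(is.infinite(D))) {
      big <- igraph::diameter(largest_connected_component(subnet),
                              unconnected = FALSE) + 1
      D[is.infinite(D)] <- big
    }
    hc <- stats::hclust(stats::as.dist(D), method = "average")
    mem <- stats::cutree(hc, k = k)
    linkage <- hc
  } else {
    comm <- igraph::cluster_fast_greedy(subnet)
    mem <- igraph::cut_at(comm, no = k)
    names(mem) <- igraph::V(subnet)$name
    linkage <- NULL
  }
  # relabel to contiguous ids in order of first appearance
  mem <- stats::setNames(match(mem, unique(mem)), names(mem))
  structure(list(membership = mem, k = k, method = method,
                 linkage = linkage),
            class = "subnetwork_clustering")
}

#' @export
print.subnetwork_clustering <- function(x, ...) {
  cat(sprintf("subnetwork_clustering: %d node(s) in %d cluster(s) [%s]\n",
              length(x$membership), x$k, x$method))
  print(table(cluster = x$membership))
  invisible(x)
}

#' Upper-tail hypergeometric overrepresentation test
#'
#' Tests whether `cluster_genes` overlaps `term_genes` more than expected
#' under uniform sampling from `universe`: p = P(X >= overlap) with
#' population N = |universe|, K = |term|, draws n = |cluster|. Genes
#' outside the universe are dropped and reported.
#'
#' @param cluster_genes character vector (the drawn set).
#' @param term_genes character vector (the annotated set).
#' @param universe nonempty character vector of background symbols.
#' @return list with `overlap`, `p`, `term_size`, `cluster_size`,
#'   `universe_size`, and counts of dropped out-of-universe genes.
#' @export
hypergeometric_enrich <- function(cluster_genes, term_genes, universe) {
  universe <- unique(normalize_symbols(universe))
  if (!length(universe)) stopf("`universe` must be nonempty")
  cg0 <- unique(normalize_symbols(cluster_genes))
  tg0 <- unique(normalize_symbols(term_genes))
  cg <- intersect(cg0, universe)
  tg <- intersect(tg0, universe)
  overlap <- length(intersect(cg, tg))
  N <- length(universe); K <- length(tg); n <- length(cg)
  p <- stats::phyper(overlap - 1, K, N - K, n, lower.tail = FALSE)
  list(overlap = overlap, p = p, term_size = K, cluster_size = n,
       universe_size = N,
       n_dropped_cluster = length(cg0) - n,
       n_dropped_term = length(tg0) - K)
}

#' Benjamini-Hochberg FDR adjustment
#'
#' Step-up adjusted q-values, returned in input order. Input p-values must
#' lie in (0, 1].
#'
#' @param pvalues numeric vector of raw p-values.
#' @return numeric vector of q-values.
#' @export
bh_fdr <- function(pvalues) {
  if (!length(pvalues)) return(numeric(0))
  if (any(!is.finite(pvalues)) || any(pvalues <= 0) || any(pvalues > 1))
    stopf("p-values must lie in (0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Per-cluster overrepresentation analysis with joint FDR
#'
#' Runs [hypergeometric_enrich()] for every (cluster, term) pair, applies
#' BH-FDR across all pairs jointly, and reports the per-cluster top terms.
#'
#' @param clustering a [cluster_subnetwork()] result.
#' @param gmt a [gene_set_collection].
#' @param universe background symbol set (must be at least as large as
#'   every cluster).
#' @param top_k number of top terms reported per cluster (ranked by
#'   ascending q, ties by ascending p then term name).
#' @param fdr_family `"joint"` (default, one BH family across all
#'   cluster-term pairs) or `"per_cluster"`.
#' @return object of class `enrichment_result` with `table` (all pairs) and
#'   `top` (per-cluster top terms); rows carry `significant = q < 0.05`.
#' @export
enrich_clusters <- function(clustering, gmt, universe, top_k = 3L,
                            fdr_family = c("joint", "per_cluster")) {
  stopifnot(inherits(clustering, "subnetwork_clustering"),
            inherits(gmt, "gene_set_collection"))
  fdr_family <- match.arg(fdr_family)
  top_k <- check_count(top_k, "top_k")
  universe <- unique(normalize_symbols(universe))
  if (!length(universe)) stopf("`universe` must be nonempty")
  clusters <- split(names(clustering$membership), clustering$membership)
  too_big <- lengths(clusters) > length(universe)
  if (any(too_big))
    stopf("universe (%d genes) is smaller than cluster(s): %s",
          length(universe), paste(names(clusters)[too_big], collapse = ", "))
  grid <- expand.grid(cluster = names(clusters), term = names(gmt),
                      stringsAsFactors = FALSE)
  rows <- lapply(seq_len(nrow(grid)), function(i) {
    h <- hypergeometric_enrich(clusters[[grid$cluster[[i]]]],
                               gmt[[grid$term[[i]]]], universe)
    data.frame(cluster = as.integer(grid$cluster[[i]]),
               term = grid$term[[i]],
               overlap = h$overlap, term_size = h$term_size,
               cluster_size = h$cluster_size, universe_size = h$universe_size,
               p = h$p)
  })
  tab <- do.call(rbind, rows)
  tab$q <- if (fdr_family == "joint") bh_fdr(tab$p)
           else stats::ave(tab$p, tab$cluster, FUN = bh_fdr)
  tab$significant <- tab$q < 0.05
  tab <- tab[order(tab$cluster, tab$q, tab$p, tab$term), , drop = FALSE]
  rownames(tab) <- NULL
  top <- do.call(rbind, lapply(split(tab, tab$cluster), function(d)
    utils::head(d, top_k)))
  rownames(top) <- NULL
  structure(list(table = tab, top = top, top_k = top_k,
                 fdr_family = fdr_family,
                 universe_size = length(universe)),
            class = "enrichment_result")
}

#' @export
print.enrichment_result <- function(x, ...) {
  cat(sprintf("enrichment_result: %d cluster-term pair(s), %d significant at q < 0.05\n",
              nrow(x$table), sum(x$table$significant)))
  cat(sprintf("top %d term(s) per cluster:\n", x$top_k))
  print(x$top[, c("cluster", "term", "overlap", "p", "q", "significant")])
  invisible(x)
}

#' Write clustering and enrichment tables as TSV
#'
#' @param clustering a `subnetwork_clustering`.
#' @param path output path.
#' @export
write_clustering <- function(clustering, path) {
  df <- data.frame(gene = names(clustering$membership),
                   cluster = as.integer(clustering$membership))
  df <- df[order(df$cluster, df$gene), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' @rdname write_clustering
#' @param enrichment an `enrichment_result`.
#' @export
write_enrichment <- function(enrichment, path) {
  utils::write.table(enrichment$table, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}
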