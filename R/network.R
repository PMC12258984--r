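# Interaction-network and gene-set container: parsing, validation and
# basic graph manipulation. Networks are simple undirected igraph objects
# whose vertex names are normalized gene symbols; block membership from
# the synthetic generator travels as the vertex attribute "block".

#' Read an interaction network from SIF or edge-list TSV
#'
#' SIF rows are `source<TAB>relation<TAB>target...` (a row may list several
#' targets, as common interactome exports do); relation types are ignored and
#' every pair becomes an undirected, unweighted edge. Edge-list rows are
#' `source<TAB>target`. Symbols are uppercased and whitespace-stripped,
#' self-loops are dropped with a warning naming their count, and duplicate
#' edges are collapsed.
#'
#' @param path file path.
#' @param format `"sif"` or `"edgelist"`.
#' @return an undirected simple `igraph` with vertex names.
#' @export
read_network <- function(path, format = c("sif", "edgelist")) {
  format <- match.arg(format)
  if (!file.exists(path)) stopf("network file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stopf("empty network file: %s", path)
  from <- character(0); to <- character(0)
  for (i in keep) {
    fields <- normalize_symbols(strsplit(lines[[i]], "\t", fixed = TRUE)[[1]])
    if (format == "sif") {
      if (length(fields) < 3L || any(!nzchar(fields)))
        stopf("malformed SIF row at line %d of %s", i, path)
      tgt <- fields[-(1:2)]
      from <- c(from, rep(fields[[1]], length(tgt)))
      to <- c(to, tgt)
    } else {
      if (length(fields) != 2L || any(!nzchar(fields)))
        stopf("malformed edge-list row at line %d of %s", i, path)
      from <- c(from, fields[[1]])
      to <- c(to, fields[[2]])
    }
  }
  make_gene_network(from, to)
}

# Assemble a simple undirected graph from endpoint vectors, dropping
# self-loops (warned) and collapsing duplicates.
make_gene_network <- function(from, to) {
  loops <- from == to
  if (any(loops))
    warnf("dropped %d self-loop edge(s)", sum(loops))
  from <- from[!loops]; to <- to[!loops]
  if (!length(from)) stopf("network has no edges after removing self-loops")
  g <- igraph::graph_from_data_frame(data.frame(from = from, to = to),
                                     directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Write a network as SIF or edge-list TSV
#'
#' @param net an `igraph` gene network.
#' @param path output path.
#' @param format `"sif"` or `"edgelist"`.
#' @param relation relation string used for SIF rows.
#' @export
write_network <- function(net, path, format = c("sif", "edgelist"),
                          relation = "interacts") {
  format <- match.arg(format)
  el <- igraph::as_edgelist(net)
  # canonical edge orientation + ordering for reproducible files
  swap <- el[, 1] > el[, 2]
  el[swap, ] <- el[swap, 2:1]
  el <- el[order(el[, 1], el[, 2]), , drop = FALSE]
  rows <- if (format == "sif")
    paste(el[, 1], relation, el[, 2], sep = "\t")
  else paste(el[, 1], el[, 2], sep = "\t")
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' Construct a gene-set collection
#'
#' @param sets named list of character vectors (term -> genes).
#' @param descriptions optional character vector of term descriptions,
#'   recycled to `length(sets)`.
#' @return object of class `gene_set_collection`: a named list of unique
#'   uppercase gene symbols with a `descriptions` attribute.
#' @export
gene_set_collection <- function(sets, descriptions = NULL) {
  if (!length(sets)) stopf("a gene-set collection must contain >= 1 term")
  nm <- names(sets)
  if (is.null(nm) || any(!nzchar(nm))) stopf("every term must be named")
  if (anyDuplicated(nm)) stopf("duplicate term name(s): %s",
                               paste(unique(nm[duplicated(nm)]), collapse = ", "))
  sets <- lapply(sets, function(g) unique(normalize_symbols(g)))
  if (any(!lengths(sets))) stopf("empty term(s) are not allowed")
  if (is.null(descriptions)) descriptions <- rep("", length(sets))
  descriptions <- rep_len(as.character(descriptions), length(sets))
  names(descriptions) <- nm
  structure(sets, descriptions = descriptions, class = "gene_set_collection")
}

#' @export
print.gene_set_collection <- function(x, ...) {
  cat(sprintf("gene_set_collection: %d term(s), sizes %d-%d\n", length(x),
              min(lengths(x)), max(lengths(x))))
  invisible(x)
}

#' Read a GMT gene-set file
#'
#' Rows are `term<TAB>description<TAB>gene1<TAB>gene2...`. Duplicate genes
#' within a term are deduplicated; a duplicate term name or a term with no
#' genes is an error.
#'
#' @param path file path.
#' @return a [gene_set_collection].
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readLines(path, encoding = "UTF-8", warn = FALSE)
  keep <- which(nzchar(trimws(lines)))
  if (!length(keep)) stopf("empty GMT file: %s", path)
  sets <- list(); descs <- character(0)
  for (i in keep) {
    fields <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(fields) < 3L)
      stopf("malformed GMT row (fewer than 3 fields) at line %d of %s", i, path)
    term <- trimws(fields[[1]])
    if (term %in% names(sets))
      stopf("duplicate term name '%s' at line %d of %s", term, i, path)
    genes <- unique(normalize_symbols(fields[-(1:2)]))
    genes <- genes[nzchar(genes)]
    if (!length(genes)) stopf("term '%s' has zero genes (line %d)", term, i)
    sets[[term]] <- genes
    descs <- c(descs, trimws(fields[[2]]))
  }
  gene_set_collection(sets, descs)
}

#' Write a gene-set collection as GMT
#'
#' @param gmt a [gene_set_collection].
#' @param path output path.
#' @export
write_gmt <- function(gmt, path) {
  descs <- attr(gmt, "descriptions")
  rows <- vapply(names(gmt), function(term) {
    paste(c(term, descs[[term]], gmt[[term]]), collapse = "\t")
  }, character(1))
  writeLines(rows, path, useBytes = TRUE)
  invisible(path)
}

#' Read / write one-symbol-per-line gene lists
#'
#' @param path file path.
#' @return normalized character vector of symbols.
#' @export
read_gene_list <- function(path) {
  if (!file.exists(path)) stopf("gene list not found: %s", path)
  x <- normalize_symbols(readLines(path, encoding = "UTF-8", warn = FALSE))
  x[nzchar(x)]
}

#' @rdname read_gene_list
#' @param genes character vector of symbols.
#' @export
write_gene_list <- function(genes, path) {
  writeLines(normalize_symbols(genes), path, useBytes = TRUE)
  invisible(path)
}

#' Induced subnetwork on a gene list
#'
#' Keeps the nodes of `net` present in `genes` and every edge with both
#' endpoints retained. Genes absent from the network are reported in the
#' graph attribute `"unmapped"` of the result.
#'
#' @param net an `igraph` gene network.
#' @param genes character vector of symbols.
#' @return the induced `igraph` subnetwork (possibly empty) with graph
#'   attribute `unmapped`.
#' @export
induced_subnetwork <- function(net, genes) {
  genes <- unique(normalize_symbols(genes))
  present <- intersect(genes, igraph::V(net)$name)
  sub <- igraph::induced_subgraph(net, present)
  igraph::graph_attr(sub, "unmapped") <- setdiff(genes, present)
  sub
}

#' Largest connected component
#'
#' Returns the component with the most nodes; ties are broken in favour of
#' the component containing the lexicographically smallest gene symbol.
#'
#' @param net a nonempty `igraph` gene network.
#' @return the component as an `igraph`.
#' @export
largest_connected_component <- function(net) {
  if (igraph::vcount(net) == 0L) stopf("empty network")
  comp <- igraph::components(net)
  best <- which(comp$csize == max(comp$csize))
  if (length(best) > 1L) {
    mins <- vapply(best, function(b)
      min(igraph::V(net)$name[comp$membership == b]), character(1))
    best <- best[order(mins)][1L]
  }
  igraph::induced_subgraph(net, which(comp$membership == best))
}
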