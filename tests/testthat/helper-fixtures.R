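# Shared fixtures: tiny graphs built in code and independent oracles.

path_graph <- function(syms) {
  igraph::graph_from_data_frame(
    data.frame(from = utils::head(syms, -1), to = utils::tail(syms, -1)),
    directed = FALSE)
}

# Disjoint cliques over the given name groups (optionally bridged).
clique_graph <- function(groups, bridges = NULL) {
  edges <- do.call(rbind, lapply(groups, function(g) t(utils::combn(g, 2))))
  if (!is.null(bridges)) edges <- rbind(edges, bridges)
  igraph::graph_from_data_frame(
    data.frame(from = edges[, 1], to = edges[, 2]), directed = FALSE)
}

barbell_graph <- function() {
  clique_graph(list(paste0("A", 1:4), paste0("B", 1:4)),
               bridges = matrix(c("A4", "B1"), 1))
}

rand_gnp_named <- function(n, p, seed) {
  g <- propnet:::local_seed(seed, igraph::sample_gnp(n, p))
  igraph::V(g)$name <- sprintf("G%04d", seq_len(n))
  g
}

# Independent dense linear-solve oracle for the diffusion fixed point,
# built from the adjacency with explicit base-R loops.
dense_rwr_oracle <- function(g, f0, alpha, mode = c("symmetric", "row")) {
  mode <- match.arg(mode)
  A <- as.matrix(igraph::as_adjacency_matrix(g))
  nodes <- rownames(A)
  d <- rowSums(A)
  W <- matrix(0, nrow(A), ncol(A), dimnames = dimnames(A))
  for (i in seq_along(d)) for (j in seq_along(d)) if (A[i, j] > 0)
    W[i, j] <- if (mode == "symmetric") 1 / sqrt(d[i] * d[j]) else 1 / d[i]
  f <- solve(diag(length(d)) - alpha * W, (1 - alpha) * as.numeric(f0[nodes]))
  stats::setNames(f, nodes)
}

ari <- function(a, b) mclust::adjustedRandIndex(a, b)

write_lines_tmp <- function(lines, ext = ".txt") {
  f <- tempfile(fileext = ext)
  writeLines(lines, f)
  f
}
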