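# Heat diffusion (random walk with restart) on an interaction network.
# The stationary heat solves F = alpha * W %*% F + (1 - alpha) * F0 with W
# the degree-normalized adjacency; with symmetric normalization and
# alpha < 1 the iteration is a contraction and convergence is guaranteed.

#' Propagation configuration
#'
#' @param alpha restart/diffusion weight in (0, 1); larger values spread
#'   heat further from the seeds.
#' @param tol convergence tolerance on the L1 change per iteration.
#' @param max_iter iteration cap.
#' @param normalization `"symmetric"` (W\[u,v\] = 1/sqrt(deg(u) deg(v)))
#'   or `"row"` (W\[u,v\] = 1/deg(u)).
#' @return a validated `propagation_config` list.
#' @export
propagation_config <- function(alpha = 0.5, tol = 1e-9, max_iter = 1000L,
                               normalization = c("symmetric", "row")) {
  normalization <- match.arg(normalization)
  alpha <- check_prob(alpha, "alpha", open_lo = TRUE, open_hi = TRUE)
  if (!is.numeric(tol) || length(tol) != 1L || !is.finite(tol) || tol < 0)
    stopf("`tol` must be a single nonnegative number")
  max_iter <- check_count(max_iter, "max_iter")
  structure(list(alpha = alpha, tol = as.numeric(tol), max_iter = max_iter,
                 normalization = normalization),
            class = "propagation_config")
}

#' Degree-normalized adjacency matrix
#'
#' @param net an `igraph` gene network (simple, undirected).
#' @param mode `"symmetric"` or `"row"`.
#' @return sparse `dgCMatrix` with node names as dimnames; rows of isolated
#'   nodes are all zero.
#' @export
normalize_adjacency <- function(net, mode = c("symmetric", "row")) {
  mode <- match.arg(mode)
  if (igraph::vcount(net) == 0L) stopf("empty network")
  A <- igraph::as_adjacency_matrix(net, sparse = TRUE)
  A <- methods::as(A, "dMatrix")
  deg <- Matrix::rowSums(A)
  inv <- ifelse(deg > 0, 1 / deg, 0)
  W <- if (mode == "symmetric") {
    s <- sqrt(inv)
    Matrix::Diagonal(x = s) %*% A %*% Matrix::Diagonal(x = s)
  } else {
    Matrix::Diagonal(x = inv) %*% A
  }
  dimnames(W) <- list(igraph::V(net)$name, igraph::V(net)$name)
  W
}

#' Seed heat vector
#'
#' Distributes unit mass uniformly over the seed genes present in the
#' network; seeds absent from the network are dropped and reported in the
#' `"unmapped"` attribute.
#'
#' @param net an `igraph` gene network.
#' @param seeds nonempty character vector of seed symbols.
#' @return named numeric vector over all network nodes summing to 1.
#' @export
make_seed_vector <- function(net, seeds) {
  seeds <- unique(normalize_symbols(seeds))
  if (!length(seeds)) stopf("`seeds` must be nonempty")
  nodes <- igraph::V(net)$name
  mapped <- intersect(seeds, nodes)
  if (!length(mapped)) stopf("no seed gene maps into the network")
  f0 <- stats::setNames(numeric(length(nodes)), nodes)
  f0[mapped] <- 1 / length(mapped)
  attr(f0, "unmapped") <- setdiff(seeds, mapped)
  f0
}

#' Iterative heat propagation
#'
#' Iterates `F <- alpha * W F + (1 - alpha) * F0` until the L1 change drops
#' below `cfg$tol` or `cfg$max_iter` is reached (in which case the result
#' carries `converged = FALSE` and a warning is raised, not an error).
#'
#' @param net an `igraph` gene network.
#' @param f0 seed vector from [make_seed_vector()] (must cover all nodes).
#' @param cfg a [propagation_config()].
#' @return named nonnegative heat vector over all nodes, with attributes
#'   `converged`, `iterations` and `config`.
#' @export
propagate <- function(net, f0, cfg = propagation_config()) {
  stopifnot(inherits(cfg, "propagation_config"))
  W <- normalize_adjacency(net, cfg$normalization)
  nodes <- rownames(W)
  if (!all(nodes %in% names(f0)))
    stopf("`f0` must assign a value to every network node")
  f0v <- as.numeric(f0[nodes])
  f <- f0v
  restart <- (1 - cfg$alpha) * f0v
  converged <- FALSE
  iter <- 0L
  while (iter < cfg$max_iter) {
    iter <- iter + 1L
    fn <- cfg$alpha * as.numeric(W %*% f) + restart
    delta <- sum(abs(fn - f))
    f <- fn
    if (delta < cfg$tol) {
      converged <- TRUE
      break
    }
  }
  if (!converged)
    warnf("propagation did not converge in %d iterations (last L1 change above tol)",
          cfg$max_iter)
  structure(stats::setNames(f, nodes), converged = converged,
            iterations = iter, config = cfg)
}

#' Closed-form heat propagation (linear solve)
#'
#' Solves `(I - alpha W) F = (1 - alpha) F0` directly. Intended as the
#' exact reference for the iterative solver on small networks.
#'
#' @inheritParams propagate
#' @param cap maximum node count for the dense solve.
#' @return named heat vector with attribute `converged = TRUE`.
#' @export
propagate_exact <- function(net, f0, cfg = propagation_config(), cap = 2000L) {
  stopifnot(inherits(cfg, "propagation_config"))
  n <- igraph::vcount(net)
  if (n > cap)
    stopf("network has %d nodes (> cap %d); use the iterative propagate()",
          n, cap)
  W <- as.matrix(normalize_adjacency(net, cfg$normalization))
  nodes <- rownames(W)
  if (!all(nodes %in% names(f0)))
    stopf("`f0` must assign a value to every network node")
  f0v <- as.numeric(f0[nodes])
  f <- solve(diag(n) - cfg$alpha * W, (1 - cfg$alpha) * f0v)
  structure(stats::setNames(as.numeric(f), nodes), converged = TRUE,
            iterations = NA_integer_, config = cfg)
}

#' Write a heat vector with its manifest
#'
#' Serializes the heat as a 2-column TSV (gene, heat) and a JSON manifest
#' recording the propagation parameters and convergence state.
#'
#' @param heat result of [propagate()] or [propagate_exact()].
#' @param path TSV output path; the manifest goes to `<path>.manifest.json`.
#' @param seed_id optional label for the seed set.
#' @export
write_heat <- function(heat, path, seed_id = NULL) {
  df <- data.frame(gene = names(heat), heat = as.numeric(heat))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  cfg <- attr(heat, "config")
  manifest <- list(seed_id = seed_id, alpha = cfg$alpha, tol = cfg$tol,
                   max_iter = cfg$max_iter, normalization = cfg$normalization,
                   iterations = attr(heat, "iterations"),
                   converged = attr(heat, "converged"),
                   n_nodes = length(heat))
  jsonlite::write_json(manifest, paste0(path, ".manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(path)
}
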