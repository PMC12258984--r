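# Heat diffusion: normalization weights, seed construction, fixed-point
# agreement with the closed-form solve, and qualitative locality.

test_that("adjacency normalization produces the stated edge weights", {
  e <- path_graph(c("A", "B"))
  W <- normalize_adjacency(e, "symmetric")
  expect_equal(W["A", "B"], 1)

  star <- igraph::graph_from_data_frame(
    data.frame(from = "C", to = c("L1", "L2", "L3")), directed = FALSE)
  Ws <- normalize_adjacency(star, "symmetric")
  expect_equal(Ws["C", "L1"], 1 / sqrt(3))
  Wr <- normalize_adjacency(star, "row")
  expect_equal(Wr["C", "L1"], 1 / 3)
  expect_equal(Wr["L1", "C"], 1)

  iso <- igraph::add_vertices(e, 1, name = "I")
  Wi <- normalize_adjacency(iso, "symmetric")
  expect_true(all(Wi["I", ] == 0))
  expect_error(normalize_adjacency(igraph::make_empty_graph(0)), "empty")
})

test_that("seed vectors spread unit mass over mapped seeds", {
  g <- path_graph(c("A", "B", "C"))
  f0 <- make_seed_vector(g, c("A", "B"))
  expect_equal(unname(f0[c("A", "B", "C")]), c(0.5, 0.5, 0))

  f1 <- make_seed_vector(g, c("a", "X"))   # normalization + unmapped
  expect_equal(unname(f1["A"]), 1)
  expect_identical(attr(f1, "unmapped"), "X")

  expect_error(make_seed_vector(g, c("X", "Y")), "no seed gene maps")
})

test_that("vanishing alpha returns the restart vector", {
  g <- rand_gnp_named(10, 0.4, seed = 1)
  f0 <- make_seed_vector(g, igraph::V(g)$name[1:3])
  h <- propagate(g, f0, propagation_config(alpha = 1e-12))
  expect_lt(max(abs(h - f0[names(h)])), 1e-9)
  he <- propagate_exact(g, f0, propagation_config(alpha = 1e-12))
  expect_lt(max(abs(he - f0[names(he)])), 1e-9)
})

test_that("symmetric two-node diffusion keeps equal heats", {
  g <- path_graph(c("A", "B"))
  f0 <- make_seed_vector(g, c("A", "B"))
  for (a in c(0.2, 0.5, 0.8)) {
    h <- propagate(g, f0, propagation_config(alpha = a, tol = 1e-12))
    expect_equal(unname(h["A"]), unname(h["B"]), tolerance = 1e-10)
  }
})

test_that("the iterative fixed point matches an independent dense solve", {
  g <- path_graph(c("A", "B", "C"))
  f0 <- make_seed_vector(g, "A")
  cfg <- propagation_config(alpha = 0.5, tol = 1e-13, max_iter = 5000)
  h <- propagate(g, f0, cfg)
  oracle <- dense_rwr_oracle(g, f0, 0.5, "symmetric")
  expect_equal(as.numeric(h[names(oracle)]), as.numeric(oracle),
               tolerance = 1e-10)

  # row-normalized variant against the same oracle
  cfg_row <- propagation_config(alpha = 0.5, tol = 1e-13, max_iter = 5000,
                                normalization = "row")
  h_row <- propagate(g, f0, cfg_row)
  oracle_row <- dense_rwr_oracle(g, f0, 0.5, "row")
  expect_equal(as.numeric(h_row[names(oracle_row)]), as.numeric(oracle_row),
               tolerance = 1e-10)
})

test_that("iterative and closed-form solvers agree on random graphs", {
  for (s in 1:10) {
    g <- rand_gnp_named(10 + 3 * s, 0.15, seed = 100 + s)
    f0 <- make_seed_vector(g, igraph::V(g)$name[1:4])
    cfg <- propagation_config(alpha = 0.6, tol = 1e-13, max_iter = 5000)
    h <- suppressWarnings(propagate(g, f0, cfg))
    he <- propagate_exact(g, f0, cfg)
    expect_lt(max(abs(h - he[names(h)])), 1e-8)
  }
  expect_error(propagate_exact(rand_gnp_named(30, 0.2, 1),
                               cap = 10,
                               f0 = make_seed_vector(rand_gnp_named(30, 0.2, 1),
                                                     "G0001")),
               "cap")
})

test_that("propagation is linear in the seed vector", {
  g <- rand_gnp_named(25, 0.2, seed = 3)
  nodes <- igraph::V(g)$name
  f0a <- make_seed_vector(g, nodes[1:5])
  f0b <- make_seed_vector(g, nodes[10:12])
  cfg <- propagation_config(alpha = 0.5, tol = 1e-13, max_iter = 5000)
  ha <- propagate(g, f0a, cfg)
  hb <- propagate(g, f0b, cfg)
  hsum <- propagate(g, stats::setNames(f0a + f0b[names(f0a)], names(f0a)),
                    cfg)
  expect_lt(max(abs(hsum - (ha + hb[names(ha)]))), 1e-9)
})

test_that("heat concentrates on the seeded module of a block model", {
  net <- generate_network(sbm_config(c(40, rep(46, 10)), 0.2, 0.01, seed = 13))
  sets <- generate_planted_sets(net,
                                planted_sets_config(1, 20, 40, 0.8, seed = 14))
  lcc <- largest_connected_component(net)
  h <- propagate(lcc, make_seed_vector(lcc, sets$seed_set))
  blocks <- stats::setNames(igraph::V(net)$block, igraph::V(net)$name)[names(h)]
  expect_gt(mean(h[blocks == 1]), mean(h[blocks != 1]))
})

test_that("hitting the iteration cap flags non-convergence without error", {
  g <- rand_gnp_named(20, 0.3, seed = 5)
  f0 <- make_seed_vector(g, "G0001")
  expect_warning(
    h <- propagate(g, f0, propagation_config(alpha = 0.9, tol = 0,
                                             max_iter = 3)),
    "did not converge")
  expect_false(attr(h, "converged"))
  expect_equal(attr(h, "iterations"), 3L)
  expect_true(all(h >= 0))
})
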