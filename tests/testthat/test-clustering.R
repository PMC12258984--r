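# Subnetwork clustering and overrepresentation: planted-structure
# recovery, exact hypergeometric tails, and BH-FDR behavior.

test_that("clustering recovers components and bridged cliques", {
  tri <- clique_graph(list(c("A1", "A2", "A3"), c("B1", "B2", "B3")))
  cl <- cluster_subnetwork(tri, 2)
  expect_equal(ari(cl$membership,
                   substr(names(cl$membership), 1, 1) == "A"), 1)

  # forcing k below the component count warns and merges components
  expect_warning(one <- cluster_subnetwork(tri, 1), "components")
  expect_true(all(one$membership == 1))

  bb <- barbell_graph()
  cl2 <- cluster_subnetwork(bb, 2)
  expect_equal(ari(cl2$membership,
                   substr(names(cl2$membership), 1, 1)), 1)
  expect_warning(cluster_subnetwork(bb, 1), NA)   # connected: k=1 is silent
  expect_true(all(cluster_subnetwork(bb, 1)$membership == 1))

  expect_error(cluster_subnetwork(tri, 7), "exceeds")
  expect_warning(
    cluster_subnetwork(clique_graph(list(c("A1", "A2", "A3"),
                                         c("B1", "B2", "B3"),
                                         c("C1", "C2", "C3"))), 2),
    "components")
})

test_that("cluster ids are contiguous and assignments are exhaustive", {
  g <- generate_network(sbm_config(c(15, 15, 15), 0.4, 0.03, seed = 61))
  cl <- cluster_subnetwork(g, 4)
  expect_setequal(unique(cl$membership), 1:4)
  expect_setequal(names(cl$membership), igraph::V(g)$name)
})

test_that("clustering is invariant to node-label permutation", {
  g <- clique_graph(list(paste0("A", 1:4), paste0("B", 1:5), paste0("C", 1:6)),
                    bridges = rbind(c("A1", "B1"), c("B2", "C1")))
  cl <- cluster_subnetwork(g, 3)
  perm <- rev(igraph::V(g)$name)
  g2 <- igraph::permute(g, match(igraph::V(g)$name, perm))
  cl2 <- cluster_subnetwork(g2, 3)
  common <- names(cl$membership)
  expect_equal(ari(cl$membership[common], cl2$membership[common]), 1)
})

test_that("hypergeometric tails match exhaustive subset enumeration", {
  # N=10, K=5, n=4, overlap=4 -> 5/210 by counting all C(10,4) draws
  u <- sprintf("G%02d", 1:10)
  term <- u[1:5]
  clus <- u[c(1:4)]
  h <- hypergeometric_enrich(clus, term, u)
  expect_equal(h$overlap, 4)
  expect_equal(h$p, 5 / choose(10, 4), tolerance = 1e-12)

  draws <- utils::combn(10, 4)
  tail_count <- sum(apply(draws, 2, function(s) sum(s %in% 1:5) >= 4))
  expect_equal(h$p, tail_count / ncol(draws), tolerance = 1e-12)

  # overlap 0 -> tail at zero is certainty
  h0 <- hypergeometric_enrich(u[6:9], u[1:3], u)
  expect_equal(h0$overlap, 0)
  expect_equal(h0$p, 1)

  # term = universe -> overlap = n and p = 1
  h1 <- hypergeometric_enrich(u[1:4], u, u)
  expect_equal(h1$overlap, 4)
  expect_equal(h1$p, 1)

  expect_error(hypergeometric_enrich("A", "A", character(0)), "nonempty")
})

test_that("out-of-universe genes are dropped and counted", {
  u <- c("A", "B", "C", "D")
  h <- hypergeometric_enrich(c("A", "Z"), c("A", "B", "Q"), u)
  expect_equal(h$cluster_size, 1)
  expect_equal(h$term_size, 2)
  expect_equal(h$n_dropped_cluster, 1)
  expect_equal(h$n_dropped_term, 1)
})

test_that("BH adjustment follows the step-up formula", {
  expect_equal(bh_fdr(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_fdr(c(0.005, 0.1)), c(0.01, 0.1))
  expect_equal(bh_fdr(0.3), 0.3)
  expect_error(bh_fdr(c(0.1, 0)), "\\(0, 1\\]")
  expect_error(bh_fdr(c(0.1, 1.2)), "\\(0, 1\\]")
  for (s in 1:5) {
    p <- propnet:::local_seed(s, stats::runif(50))
    q <- bh_fdr(p)
    expect_true(all(diff(q[order(p)]) >= -1e-15))
    expect_true(all(q <= 1 & q >= p))
  }
})

test_that("a planted term tops its cluster with joint FDR significance", {
  net <- generate_network(sbm_config(c(25, 25, 25), 0.35, 0.02, seed = 71))
  sets <- generate_planted_sets(net,
                                planted_sets_config(1, 10, 24, 0.75, seed = 72))
  gmt <- generate_gmt(net, 10, 12, planted_term_block = 1, seed = 73)
  sub <- induced_subnetwork(net, sets$query_set)
  cl <- cluster_subnetwork(sub, 2)
  enr <- enrich_clusters(cl, gmt, universe = igraph::V(net)$name)
  # the cluster holding the in-block query genes should rank PLANTED_TERM first
  blocks <- stats::setNames(igraph::V(net)$block, igraph::V(net)$name)
  in_cluster <- names(which.max(tapply(blocks[names(cl$membership)] == 1,
                                       cl$membership, mean)))
  top_row <- enr$top[enr$top$cluster == as.integer(in_cluster), ][1, ]
  expect_equal(top_row$term, "PLANTED_TERM")
  expect_lt(top_row$q, 0.05)
  expect_true(all(enr$table$q >= enr$table$p - 1e-12))
})

test_that("non-overlapping collections give p = 1 and stable tie order", {
  g <- clique_graph(list(c("A1", "A2", "A3", "A4")))
  cl <- cluster_subnetwork(g, 1)
  gmt <- gene_set_collection(list(TB = c("Z1", "Z2"), TA = c("Z3", "Z4")))
  u <- c(igraph::V(g)$name, paste0("Z", 1:4))
  enr <- enrich_clusters(cl, gmt, u, top_k = 2)
  expect_true(all(enr$table$p == 1))
  expect_false(any(enr$table$significant))
  expect_equal(enr$top$term, c("TA", "TB"))  # lexicographic on full ties
  expect_error(enrich_clusters(cl, gmt, universe = c("A1", "A2")), "smaller")
})
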