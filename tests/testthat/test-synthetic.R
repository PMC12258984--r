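# Synthetic-data generators: determinism, degenerate configurations, and
# agreement of planted structure with its closed-form expectations.

test_that("degenerate block models produce the exact expected graphs", {
  g <- generate_network(sbm_config(c(4, 4), p_in = 1, p_out = 0, seed = 1))
  expect_equal(igraph::vcount(g), 8)
  expect_equal(igraph::ecount(g), 12)  # two disjoint 4-cliques
  expect_equal(igraph::components(g)$no, 2)

  g0 <- generate_network(sbm_config(3, p_in = 0, p_out = 0, seed = 1))
  expect_equal(igraph::vcount(g0), 3)
  expect_equal(igraph::ecount(g0), 0)

  expect_error(sbm_config(c(0, 4), 0.5, 0.1), "positive integers")
  expect_error(sbm_config(c(4, 4), 1.5, 0.1), "p_in")
  expect_warning(sbm_config(c(4, 4), 0.1, 0.5), "assortative")
})

test_that("network generation is a pure function of config and seed", {
  cfg <- sbm_config(c(20, 20), 0.3, 0.05, seed = 7)
  g1 <- generate_network(cfg)
  g2 <- generate_network(cfg)
  expect_identical(igraph::as_edgelist(g1), igraph::as_edgelist(g2))
  expect_identical(igraph::V(g1)$block, igraph::V(g2)$block)
  g3 <- generate_network(sbm_config(c(20, 20), 0.3, 0.05, seed = 8))
  expect_false(identical(igraph::as_edgelist(g1), igraph::as_edgelist(g3)))
})

test_that("within-block edge counts match the binomial expectation", {
  n_pairs <- 2 * choose(50, 2)
  expected <- 0.2 * n_pairs
  sd3 <- 3 * sqrt(n_pairs * 0.2 * 0.8 / 100)  # sd of the mean over 100 seeds
  counts <- vapply(1:100, function(s) {
    g <- generate_network(sbm_config(c(50, 50), 0.2, 0.01, seed = s))
    el <- igraph::as_edgelist(g)
    b <- stats::setNames(igraph::V(g)$block, igraph::V(g)$name)
    sum(b[el[, 1]] == b[el[, 2]])
  }, numeric(1))
  expect_lt(abs(mean(counts) - expected), sd3)
})

test_that("planted sets respect the proximity fraction and determinism", {
  net <- generate_network(sbm_config(c(30, 70), 0.3, 0.05, seed = 3))
  block1 <- igraph::V(net)$name[igraph::V(net)$block == 1]

  s1 <- generate_planted_sets(net, planted_sets_config(1, 10, 20, 1, seed = 5))
  expect_length(s1$query_set, 20)
  expect_true(all(s1$query_set %in% block1))
  expect_true(all(s1$seed_set %in% block1))

  s0 <- generate_planted_sets(net, planted_sets_config(1, 10, 20, 0, seed = 5))
  expect_length(intersect(s0$query_set, block1), 0)

  sh <- generate_planted_sets(net,
                              planted_sets_config(1, 10, 20, 0.6, seed = 5))
  expect_equal(sum(sh$query_set %in% block1), round(0.6 * 20))

  again <- generate_planted_sets(net,
                                 planted_sets_config(1, 10, 20, 0.6, seed = 5))
  expect_identical(sh, again)

  expect_error(
    generate_planted_sets(net, planted_sets_config(1, 31, 20, 1, seed = 1)),
    "seed_size")
  expect_error(
    generate_planted_sets(net, planted_sets_config(1, 10, 40, 1, seed = 1)),
    "target block")
})

test_that("null DE tables give uniform p-values and fixed seeds reproduce", {
  rejections <- vapply(1:20, function(s) {
    de <- generate_de_table(de_config(2000, 0, 4, 5, 0.5, seed = s))
    suppressWarnings(stats::ks.test(de$pvalue, "punif")$p.value) < 0.01
  }, logical(1))
  expect_gte(mean(!rejections), 0.95)

  de1 <- generate_de_table(de_config(200, 0.2, 3, 5, 0.5, seed = 11))
  de2 <- generate_de_table(de_config(200, 0.2, 3, 5, 0.5, seed = 11))
  expect_identical(de1, de2)
  expect_error(de_config(100, 0.2, 3, 1, 0.5), "n_replicates_per_group")
})

test_that("planted DE effects pass the fold-change filter at high power", {
  de <- generate_de_table(de_config(1000, 0.5, 4, 5, 0.5, seed = 21))
  reg <- de[de$regulated, ]
  expect_gte(mean(abs(reg$log2fc) > 2 & reg$pvalue < 0.05), 0.9)
})

test_that("gene-set generation plants one extra term inside its block", {
  net <- generate_network(sbm_config(c(30, 70), 0.3, 0.05, seed = 3))
  gmt <- generate_gmt(net, n_terms = 5, term_size = 10,
                      planted_term_block = 1, seed = 9)
  expect_length(gmt, 6)
  expect_true(all(lengths(gmt) == 10))
  block1 <- igraph::V(net)$name[igraph::V(net)$block == 1]
  expect_true(all(gmt[["PLANTED_TERM"]] %in% block1))
  expect_identical(gmt, generate_gmt(net, 5, 10, 1, seed = 9))
  expect_error(generate_gmt(net, 5, 0, 1, seed = 9), "term_size")
})

test_that("regulon generation plants activity with the stated effect", {
  r0 <- generate_regulons(6, 5, active_fraction = 0, effect_lfc = 2,
                          seed = 4, noise_sd = 0.1)
  expect_length(r0$active_regulators, 0)
  expect_false(any(r0$de$regulated))
  expect_lt(abs(mean(r0$de$log2fc)), 0.1)   # pure noise around zero

  r1 <- generate_regulons(6, 30, active_fraction = 0.5, effect_lfc = 2,
                          seed = 4, noise_sd = 0.1, prob_repression = 0)
  active_targets <- r1$regulons$target[
    r1$regulons$regulator %in% r1$active_regulators]
  m <- mean(r1$de$log2fc[match(active_targets, r1$de$feature_id)])
  expect_lt(abs(m - 2), 0.1)                # weights all +1 -> mean lfc ~ 2

  expect_identical(r1, generate_regulons(6, 30, 0.5, 2, seed = 4,
                                         noise_sd = 0.1,
                                         prob_repression = 0))
  expect_error(generate_regulons(3, 2, 0.5, 2), "targets_per")
})
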