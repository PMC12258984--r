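# propnet

Network-propagation proximity testing, subnetwork enrichment, and regulon
activity scoring for omics gene lists.

## The problem

A recurring question in systems biology: given a list of genes or proteins
that respond to some condition (say, upregulated transcripts in patient
samples, or proteins induced by a conditioned-media treatment), are they
*functionally close* — on a molecular interaction network — to a set of
genes already implicated in a disease, such as the transcriptionally
upregulated, copy-number-amplified, or recurrently mutated genes of a tumor
cohort? Direct overlap between such lists is usually small; network
proximity captures shared pathway membership that overlap misses.

`propnet` implements that analysis as a reusable, fully testable pipeline:

1. **Heat diffusion** (random walk with restart) from a *seed* gene set
   over an undirected interaction network (SIF or edge-list input).
2. A **median-heat proximity statistic** for a *query* gene set, with an
   **empirical p-value** against size-matched random gene sets.
3. **Induced-subnetwork extraction** and **hierarchical clustering** into
   interconnected subclusters.
4. Per-cluster **hypergeometric overrepresentation** against a GMT gene-set
   collection with Benjamini–Hochberg FDR.
5. Differential-expression **threshold filters** (|log2FC|, p) and gene-list
   set algebra (intersection, union, size matching).
6. A transparent **regulon activity scorer** (weighted-mean statistic with a
   gene-label permutation z-score) for TF/kinase-style regulons.
7. A **synthetic-data layer** (stochastic block models with planted modules,
   planted gene sets, DE tables, gene-set collections, regulons) so every
   stage is testable without downloading any external resource.

## The statistics

Propagation solves the random-walk-with-restart fixed point

    F = alpha * W F + (1 - alpha) * F0,

equivalently `F = (1 - alpha) (I - alpha W)^{-1} F0`, where
`W = D^{-1/2} A D^{-1/2}` is the symmetrically degree-normalized adjacency
matrix and `F0` puts unit mass uniformly on the seed genes. With
`0 < alpha < 1` the iteration is a contraction, so the iterative solver and
the dense linear solve (`propagate_exact()`) agree to numerical precision —
that equivalence is part of the test suite.

The proximity of a query set Q is `median(F[Q])`, compared against the
medians of `n_random` sets of size |Q| drawn uniformly from the network;
the default empirical p-value is the permutation estimator
`p = (1 + #{r >= obs}) / (N + 1)` (a rank-based convention is available).

Cluster overrepresentation uses the upper hypergeometric tail
`P(X >= k)` with population N = |universe|, K = |term|, n = |cluster|,
BH-adjusted across all cluster×term pairs. Regulator activity is
`m = sum(w_i x_i) / sum(|w_i|)` over regulon targets with
`z = (m_obs - mean(m_perm)) / sd(m_perm)` under permutation of the
fold-change vector.

## Worked example

All-synthetic, seeded, and reproducible: a 500-node modular network with a
40-node planted "cancer" module, a 20-gene seed set inside the module, and
a 40-gene query set with 80% of its members drawn from the module.

```r
library(propnet)

net  <- generate_network(sbm_config(c(40, rep(46, 10)), p_in = 0.2,
                                    p_out = 0.01, seed = 1))
sets <- generate_planted_sets(net,
          planted_sets_config(1, seed_size = 20, query_size = 40,
                              proximity = 0.8, seed = 2))
res  <- run_proximity_test(net, sets$seed_set, sets$query_set,
          prox_cfg = proximity_config(n_random = 1000, rng_seed = 3))
res
#> Network proximity test
#>   nodes: 500 | seeds mapped: 20 | query used: 40
#>   observed median heat: 0.006851
#>   random medians (n = 1000): median 0.000311793
#>   empirical p (plus_one): 0.000999
```

The query's median heat (0.0069) is ~20x the typical random-set median
(0.0003); none of the 1000 size-matched random sets reaches it, so the
empirical p-value is at its floor, 1/1001.

Clustering the query subnetwork and testing each cluster against a gene-set
collection with one term planted in the same module:

```r
gmt <- generate_gmt(net, n_terms = 10, term_size = 15,
                    planted_term_block = 1, seed = 4)
sub <- largest_connected_component(induced_subnetwork(net, sets$query_set))
cl  <- cluster_subnetwork(sub, k = 2)
enr <- enrich_clusters(cl, gmt, universe = igraph::V(net)$name)
enr
#> enrichment_result: 22 cluster-term pair(s), 1 significant at q < 0.05
#> top 3 term(s) per cluster:
#>   cluster           term overlap            p            q significant
#> 1       1   PLANTED_TERM      10 6.394787e-10 1.406853e-08        TRUE
#> 2       1 RANDOM_TERM_10       2 2.482643e-01 1.000000e+00       FALSE
#> ...
```

The planted term tops the module-derived cluster at q ≈ 1.4e-08; every
random term stays non-significant.

The whole pipeline (simulate → filter → proximity → cluster → enrich →
activity, with a JSON run manifest) runs from one config:

```r
run_all(demo_config(seed = 11), "demo_out")
```

or from the shell via the bundled CLI
(`system.file("exec/propnet", package = "propnet")`):

```sh
propnet run-all --seed 11 --out demo_out
propnet proximity --network net.sif --seeds seeds.txt --query query.txt \
    --n-random 1000 --alpha 0.5 --seed 17 --out result.json
```

Identical config + seed gives byte-identical output trees.

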