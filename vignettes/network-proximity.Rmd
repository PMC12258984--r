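---
title: "Network proximity, subnetwork enrichment, and regulon activity: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Network proximity, subnetwork enrichment, and regulon activity: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(propnet)
```

`propnet` asks a single scientific question in several guises: is a gene or
protein list functionally close, on a molecular interaction network, to a
set of genes already tied to a phenotype? This vignette explains the models
behind each stage, the parameters that matter, the numerical choices, what
the synthetic data does and does not emulate, and the design decisions that
were genuinely open.

## The diffusion model

The network is a simple undirected graph over gene symbols (symbols are
uppercased and whitespace-stripped on input, so lists with mixed casing
intersect correctly; no identifier cross-mapping is attempted). Heat
diffusion solves the random-walk-with-restart fixed point

$$F \;=\; \alpha\, W F + (1-\alpha) F_0,$$

with $W = D^{-1/2} A D^{-1/2}$ the symmetrically degree-normalized
adjacency and $F_0$ unit mass spread uniformly over the seed genes.
Because $\|\alpha W\|_2 \le \alpha < 1$, the iteration contracts and
converges geometrically; `propagate_exact()` solves
$(I-\alpha W)F = (1-\alpha)F_0$ directly and serves as the exact reference
(the suite asserts agreement below $10^{-8}$ on random graphs).

Published descriptions of "diffuse heat" propagation frequently omit the
kernel, restart weight, normalization and stopping rule, and those details
change the numbers. This package therefore fixes and discloses one
formulation rather than claiming to recover anyone else's: symmetric
normalization, `alpha = 0.5`, L1 stopping tolerance `1e-9`, `max_iter =
1000`. All four are configurable (`propagation_config()`), recorded in the
run manifest, and a row-stochastic normalization is available as a switch.
Hitting the iteration cap flags the result (`converged = FALSE`, a
warning), it does not error: a flagged result is still interpretable and
the flag travels into the manifest.

Two further choices were open:

* **Seed mass.** Uniform over mapped seeds, not degree-weighted — the
  simplest defensible default; unmapped seeds are dropped and reported.
* **Disconnected networks.** Propagation runs on the largest connected
  component (ties broken toward the component holding the
  lexicographically smallest symbol). Off-component query genes keep heat
  exactly 0 and *remain in the statistic* — dropping them silently would
  bias the proximity upward.

## The proximity test

The statistic is the median heat over the query genes. The null is
*size-matched random gene sets* drawn uniformly from the full node set —
no degree matching, because the data-generating designs this mirrors state
size matching only; the universe choice is explicit and logged. All random
medians are read off the **same** heat vector as the observed median; one
propagation per test, which the suite verifies by reconstructing the
random medians from an independently computed heat vector.

Two p-value conventions are implemented:

* `plus_one` (default): $p = (1 + \#\{r \ge \mathrm{obs}\})/(N+1)$, the
  standard permutation estimator — never zero, floor $1/(N+1)$.
* `rank_over_n`: the rank of the observed median in the descending pooled
  list divided by $N$, with tied null values placed ahead of the observed
  value (conservative). This reproduces the "rank the medians, divide the
  position by the number of randomizations" rule sometimes reported in the
  literature; with $N = 1000$ the two differ by less than $10^{-3}$.

Seed∩query overlap is *kept* in the statistic by default
(`exclude_seed_overlap = FALSE`): in disease applications that overlap is
itself biologically meaningful. Excluding it removes seed genes from both
the query and the sampling universe.

Under the null (query drawn by the same uniform rule as the random sets),
$P(p \le t) = \lfloor t(N{+}1)\rfloor/(N{+}1) \le t$: the estimator is
exactly calibrated up to discreteness, which the suite checks with a KS
test over 200 independent null tests.

## Subnetwork clustering and overrepresentation

"Hierarchical clustering of an interaction subnetwork" admits many
readings; the package commits to the simplest reproducible one:
agglomerative **average linkage on shortest-path hop distances**, cut to
exactly `k` clusters. Node pairs in different components are assigned the
diameter of the largest component plus one, so components separate before
any intra-component split; asking for fewer clusters than components
warns. A greedy-modularity alternative sits behind a config switch as a
robustness check. `k` is a user decision, not an estimated quantity — the
method will not tell you the "true" number of modules.

Overrepresentation of each cluster in each gene-set term is the upper
hypergeometric tail $P(X \ge k)$ with population $N$ = universe size,
$K$ = term size, $n$ = cluster size. The universe defaults to **all
network nodes**; published analyses rarely state their background, and the
choice materially changes p-values, so here it is explicit, configurable
and logged. BH-FDR is applied across all cluster×term pairs jointly
(matching a single heatmap-wide significance threshold); a per-cluster
family is available. Per-cluster top-k terms are ranked by ascending q,
ties by ascending p then term name — fully deterministic.

## Threshold filters and list algebra

Differential-statistics tables carry `feature_id`, `log2fc`, `pvalue`
(extra columns preserved; p-values must lie in (0, 1]). Filters apply
**strict** inequalities, exactly as printed in the usual captions
(|log2FC| > 2 and p < 0.05 for transcript lists; > 1 for protein and
phosphosite lists): boundary rows are excluded, and the suite pins that
behavior. The p filtered on is the raw p by default — captions that say
"p < 0.05" usually mean unadjusted — with a BH option off by default.
Intersection, union (with per-source membership) and top-n size matching
(by |log2FC| or p, symbol tie-breaks) operate on normalized symbols.

`filter_power()` computes the filter's analytic power under the
generator's two-group normal model by deterministic quadrature: given the
two sample variances, the mean difference is independent and normal, so
$P(|\hat\Delta| > \max(c,\; t_{\mathrm{crit}}(\nu_W)\,\widehat{se}))$ has
a closed form per variance pair; integrating over a 160-point chi-square
quantile midpoint grid per axis gives ~3-digit accuracy, ample against
Monte-Carlo error at the tested sizes.

## Regulon activity

The scorer is deliberately minimal: for a regulon with signed weights
$w$ over targets with fold changes $x$,
$m = \sum_i w_i x_i / \sum_i |w_i|$, and significance comes from permuting
the fold-change vector across **all** features ($z$-score and plus-one
empirical p). Shuffling across features rather than within regulons
preserves each regulon's size and weight structure under the null. The
statistic is invariant to positive rescaling of a regulon's weights and
anti-symmetric under negation of the fold changes; a zero permutation sd
(constant fold-change vector) yields z = 0 with a `degenerate` flag rather
than NaN. Regulators with fewer than `min_targets` (default 3) mapped
targets are skipped and reported.

This module is an explicit simplification of motif-matrix kinase scoring
and multi-method TF-activity frameworks: it implements one transparent
statistic sufficient to exercise and test the activity-*ranking* stage.
Its scores are not expected to match any particular external tool.

## What the synthetic data emulates — and what it does not

* **Networks** are stochastic block models (planted partition): a tunable
  notion of module proximity with none of the scale-free degree
  heterogeneity, hubs, or annotation bias of curated interactomes.
  Degree-uniformity is why size-matched (rather than degree-matched)
  random sets are exactly calibrated here; on real networks with strong
  hubs, degree-aware nulls are a prudent robustness check.
* **Seed/query sets** are planted by block membership with a `proximity`
  fraction; `proximity = 0.8` against a 40-node module in a 500-node
  network is the package's canonical "signal present" condition, and
  uniform sampling is the "null" condition.
* **DE tables** are two-group normal log-scale replicates with a Welch
  t-test — a stand-in for count-model or intensity-model fits, adequate
  because downstream stages consume only (log2FC, p). No batch structure,
  missingness, or variance trends are simulated.
* **Regulons** get balanced activating/repressing weights by default
  (`prob_repression = 0.5`). This keeps the global fold-change
  distribution centered when activity is planted, so the gene-label
  permutation null stays unbiased for inactive regulators; skewed regulon
  sign structure (realistic for some TFs) shifts it, and the parameter
  exposes exactly that effect. The paired p-values are two-sided normal
  tails of `log2fc / noise_sd` — uniform under the null — since the
  activity scorer consumes only fold changes.

Every generator is a pure function of its configuration including the
seed, so all tests and the demo pipeline are bit-reproducible. Passing
tests on these conditions demonstrates correctness of the machinery and
calibration under the stated models — not performance on any real
interactome or cohort.

## Pipeline and reproducibility

`run_all()` executes simulate/load → filter → proximity (per seed
category) → subnetwork → cluster → enrich → activity from one config
(`demo_config()` or YAML; see `inst/extdata/demo_config.yaml`), writing
TSV/JSON outputs plus a JSON manifest: config echo, package version,
per-stage seeds, input MD5 checksums, proximity summaries and accumulated
warnings. Stage seeds derive from the one global seed by stable hashing of
stage names, so adding a stage never perturbs earlier stages' randomness.
The manifest deliberately records no wall-clock state, so two runs with
the same config and seed produce **byte-identical** output trees — the
property the suite asserts. A thin CLI (`inst/exec/propnet`) maps
subcommands onto the exported functions.

## Problem sizes used by the test suite

Chosen as the package's own study conditions: solver/oracle agreement on
50 random graphs of up to 50 nodes at $\alpha \in \{0.1, 0.5, 0.9\}$;
calibration over 200 null proximity tests (200 random sets each) on a
300-node six-block network; power over 20 replicates of the 500-node
planted-proximity condition with 1000 random sets; exhaustive
hypergeometric enumeration for all configurations with $N \le 12$; filter
recall on 2000-feature tables; activity recovery over 20 seeds with 1000
permutations. The full suite runs in well under a minute on one core.

## Known limitations

* Unweighted, undirected edges only; SIF relation types are ignored. No
  heat-kernel (matrix-exponential) variant.
* No identifier mapping between Entrez/Ensembl/UniProt — inputs must be
  symbol-keyed.
* Cluster counts are user-supplied; the dissimilarity/linkage choice is
  one defensible reading of "hierarchical clustering of a subnetwork",
  not a canonical one.
* The activity scorer is a single statistic, not a consensus framework,
  and handles no phosphosite flanking sequences.
* Analytic counts from any particular published analysis (e.g. specific
  DEG totals) are not reproducible from this package alone: they require
  the original raw data and the exact network release and kernel, which
  are not part of the artifact.
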