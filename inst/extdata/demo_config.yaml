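# All-synthetic demo configuration for `run_all()` / `propnet run-all`.
# Mirrors demo_config(): a modular network with one planted disease
# module, planted seed/query sets at proximity 0.8, a DE table, a gene-set
# collection with one planted term, and planted-active regulons.
seed: 11
simulate:
  network:
    block_sizes: [30, 35, 35]
    p_in: 0.25
    p_out: 0.02
  sets:
    target_block: 1
    seed_size: 12
    query_size: 20
    proximity: 0.8
  de:
    n_features: 400
    frac_regulated: 0.2
    effect_lfc: 3
    n_replicates_per_group: 5
    sigma: 0.5
  gmt:
    n_terms: 8
    term_size: 12
    planted_term_block: 1
  regulons:
    n_regulators: 10
    targets_per: 8
    active_fraction: 0.3
    effect_lfc: 2
    noise_sd: 0.1
proximity:
  n_random: 500
clustering:
  k: 3
activity:
  n_perm: 500
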