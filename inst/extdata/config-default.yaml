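# Default pivotnet pipeline configuration: a synthetic seven-stage
# study with two planted co-expression modules, three planted pivot
# hubs and one planted 4-cell vs 8-cell differential contrast.
seed: 1
synthetic:
  n_genes: 200
  stages: [oocyte, zygote, 2cell, 4cell, 8cell, morula, blastocyst]
  replicates_per_stage: 3
  modules:
    - [20, 0.9]
    - [20, 0.9]
  n_pivots: 3
  pivot_strength: 0.9
  de:
    - {stage_a: 4cell, stage_b: 8cell, n_de: 20, fold_change: 3}
  noise_sd: 0.5
  ppi: {p_within: 0.9, p_hub_to_module: 0.8333333, p_background: 0.01, hub_min_degree: 12}
  go: {terms_per_module: 3, annotation_noise: 0.05}
thresholds:
  tpm_threshold: 1        # TPM strictly above this ...
  replicate_fraction: 0.5 # ... in strictly more than this fraction of a stage's replicates
  edge_q: 0.01            # BH-adjusted PCC significance for network edges
  min_module_size: 10     # functional modules need at least this many genes
  enrichment_q: 0.05      # ... and one GO term at this BH cutoff
  hub_min_degree: 10      # inter-modular hubs interact with at least this many genes
  pivot_p: 0.05           # hypergeometric cutoff for pivot calls
  de_q: 0.05              # DE: BH-adjusted p strictly below
  fold_change: 1.4        # DE: linear fold change strictly above
mcl:
  inflation: 2
  expansion: 2
  loop_weight: 1
  prune_threshold: 1.0e-05
  max_iterations: 100
  tolerance: 1.0e-06
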