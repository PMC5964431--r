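# metcovnet

Group-level **metabolic covariance brain networks** from parcellated
regional glucose-uptake (FDG-PET SUVR-like) signals, and their comparison
between cohorts.

Neuroimaging groups studying degenerative dementia ask whether disease
reorganizes the brain's metabolic architecture beyond shifting regional
means. The approach implemented here treats the 90 regions of an AAL-style
parcellation as nodes and the inter-subject covariation of regional uptake
as edges, then compares graph topology between a patient-like and a
control-like cohort (canonically 22 subjects each):

* **Network construction** — per-subject whole-brain z-normalization, a
  shrinkage **partial-correlation** matrix per group
  (`R_ij = -Ω_ij / √(Ω_ii Ω_jj)`, `Ω = inv((1-λ)S + λ diag(S))`), and
  binarization that keeps the top `floor(s · N(N-1)/2)` pairs by `|R|`
  at sparsity `s` (841 edges at the headline `s = 0.21`, N = 90).
* **Graph metrics** — clustering `C`, harmonic characteristic path length
  `L = 1 / mean(1/d_ij)`, global and local efficiency, and small-world
  indices `γ = C/C_rand`, `λ = L/L_rand`, `σ = γ/λ` against 200
  degree-preserving rewired null networks; hubs are nodes with normalized
  betweenness `b_i = B_i / mean(B) > 1.5`.
* **Inference** — nonparametric group-reassignment permutation tests
  (add-one p-values) for metric curves across a 6–40% sparsity grid and
  for per-region hub alterations.
* **Seed correlation** — voxel-wise Pearson r-maps against a seed region,
  Fisher `z = ½ ln((1+r)/(1-r))`, the two-sample deviate
  `z = (z₁ - z₂)/√(1/(n₁-3) + 1/(n₂-3))`, and a Benjamini–Hochberg FDR
  mask at `q = 0.05`, split into strengthened and weakened voxel sets.
* **Synthetic cohorts** — a first-class generator
  (`build_modular_covariance`, `simulate_cohort_pair`,
  `make_toy_atlas`, `render_subject_volumes`) emulating two cohorts with a
  modular small-world covariance backbone and planted hub alterations, so
  the whole chain is testable without clinical data.

## Worked example

The numbered scripts under `analysis/` run the full study on a simulated
cohort pair in which group B carries one planted hub reorganization
(region 17 decouples from its community and bridges to all others):

```sh
Rscript analysis/01_simulate_cohorts.R
Rscript analysis/02_build_networks.R
Rscript analysis/03_graph_metrics.R
Rscript analysis/04_group_comparison.R
Rscript analysis/05_seed_correlation.R
```

Stage 3 prints the per-group network parameters at sparsity 0.21:

```
Group A: C = 0.773  L = 1.811  sigma = 3.572
Group B: C = 0.834  L = 1.792  sigma = 3.569
Both sigma > 1: TRUE - small-world topology in both groups.
```

`sigma > 1` (clustering far above matched random networks at comparable
path length) is the small-world signature expected of brain networks.
Stage 4 screens all 90 regions for altered hubs; the planted region tops
the list:

```
Smallest hub-comparison p-values (region: bi_A vs bi_B, p):
   region 17: 0.22 vs 28.30, p = 0.0020
   region 37: 0.08 vs 2.55, p = 0.0030
   ...
```

Region 17's normalized betweenness jumps from 0.22 (an ordinary community
member in group A) to 28.3 (the dominant inter-community bottleneck in
group B), with a 1000-permutation p of 0.002. Stage 5 then uses that
region as the seed for the voxel-wise comparison and reports the
FDR-significant strengthened/weakened voxel sets as NIfTI masks plus a
per-region summary table.

Equivalent programmatic use:

```r
library(metcovnet)
sim <- simulate_cohort_pair(
  seed = 1, alterations_b = list(list(region = 17, mode = "strengthen")))
net <- binarize_by_sparsity(
  partial_correlation_matrix(normalize_region_matrix(sim$cohort_a)), 0.21)
network_metrics(net$A, n_null = 200, seed = 1)
compare_hub_bi(sim$cohort_a, sim$cohort_b, sparsity = 0.21, n_perm = 1000)
```

`run_pipeline(pipeline_config(...), out_dir)` executes all stages from one
configuration and writes TSV tables, NIfTI maps, and a JSON manifest.

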