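---
title: "Metabolic covariance brain networks: models, estimators, and design choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Metabolic covariance brain networks: models, estimators, and design choices}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(metcovnet)
```

## The scientific problem

Regional glucose uptake measured with FDG-PET gives one number per brain
region per subject. A *metabolic covariance network* treats the regions of
an anatomical parcellation (here 90, AAL-style) as nodes and the
inter-subject covariation of their uptake as edges: two regions are
"connected" when subjects with high uptake in one tend to have high uptake
in the other. Comparing the graph topology of such networks between a
patient cohort and controls — clustering, path length, efficiency,
small-worldness, and betweenness hubs — asks whether disease reorganizes
the brain's metabolic architecture rather than just shifting regional
means. The canonical contrast this package is built around is two cohorts
of 22 subjects each, a size at which every estimation step must be treated
as noisy.

## The pipeline

1. **Preprocessing** (`smooth_volume`, `rescale_grayscale`,
   `extract_region_means`, `normalize_subject_signals`): volumes already in
   a common atlas space are optionally smoothed with a Gaussian kernel
   (FWHM in mm; per-axis sigma `fwhm / (voxel * sqrt(8 log 2))`, edge
   replication at boundaries), optionally min–max rescaled to `[0, 255]`,
   reduced to per-region means, and each subject is z-normalized by their
   whole-brain mean and standard deviation.
2. **Network construction** (`partial_correlation_matrix`,
   `binarize_by_sparsity`): the group's subjects × regions table yields a
   shrinkage partial-correlation matrix; the N(N−1)/2 region pairs are
   ranked by |R| and the top `floor(s · N(N−1)/2)` become edges at sparsity
   `s` (841 edges at the headline s = 0.21 for N = 90). Negative
   correlations enter through their absolute value; ties break
   lexicographically so the rule is deterministic and purely rank-based.
3. **Graph metrics** (`network_metrics`): clustering coefficient C,
   harmonic characteristic path length L (reciprocal of the mean reciprocal
   shortest-path length, so disconnected pairs contribute zero and
   `L · E_glob = 1`), global and local efficiency, and betweenness
   centrality normalized by its network mean (`bi = B_i / mean(B)`), with
   `bi > 1.5` defining hubs. Small-world indices compare C and L with their
   means over 200 degree-preserving rewired null networks:
   `gamma = C/C_rand`, `lambda = L/L_rand`, `sigma = gamma/lambda`.
4. **Inference** (`permutation_test_statistic`, `metric_sparsity_curves`,
   `compare_hub_bi`): group labels are permuted preserving group sizes and
   the full chain is recomputed per relabeling; p-values use the add-one
   convention `(1 + #qualifying)/(1 + n_perm)`, so they are never zero.
   Relabelings are drawn on a content-sorted pooled ordering, which makes
   two-sided results invariant to the cohort argument order.
5. **Seed correlation** (`seed_group_compare`): a seed region's mean signal
   is correlated with every in-mask voxel across subjects per group; Fisher's
   `z = atanh(r)` and the two-sample deviate
   `z = (z1 − z2)/sqrt(1/(n1−3) + 1/(n2−3))` give voxel-wise two-sided
   p-values, masked by Benjamini–Hochberg FDR at q = 0.05.

## Key parameters

| Parameter | Default | Meaning |
|---|---|---|
| `sparsity` | 0.21 | fraction of region pairs kept as edges at the headline threshold |
| `sparsity_grid()` | 0.06–0.40 by 0.01 | grid for metric curves and connectivity scans |
| `shrinkage` | 0.7 | diagonal shrinkage of the sample covariance before inversion |
| `n_null` | 200 | rewired null networks behind gamma/lambda/sigma |
| `n_perm` | 2000 (curves), 1000 (hubs) | permutation relabelings |
| `hub_threshold` | 1.5 | strict bi cutoff for hub status |
| `q` | 0.05 | FDR level for voxel-wise seed comparison |

**Why shrinkage 0.7.** With p = 90 regions and n = 22 subjects the sample
covariance is singular; the estimator inverts
`S* = (1 − λ) S + λ diag(S)`. Small λ leaves the inversion dominated by
sampling noise; large λ makes the ranking of |R| (all that binarization
consumes) approach the stable marginal-correlation ranking. We found λ =
0.7 a good stability compromise in simulation and kept λ configurable,
with a Moore–Penrose pseudo-inverse estimator (`estimator =
"pseudoinverse"`) as an alternative; the difference between estimators is
most visible in which borderline edges enter near the sparsity cutoff.

## The synthetic cohort generator

No clinical cohort ships with the package, so a generator stands in for
one; its defaults *are* the package's study conditions and the tests'
power statements refer to them.

Two covariance families are provided:

* `build_group_covariance()` — a ring-lattice construction
  (`I(1 + load) + strength · A` over a Watts–Strogatz-style lattice). It is
  simple and convenient for small examples and null checks, but a circulant
  lattice covariance caps achievable edge correlations at
  `1/|λ_min(A)| ≈ 0.3` for lattice degree 8 — the same magnitude as the
  sampling noise of a correlation at n = 22 (sd ≈ 0.21). Networks estimated
  from it are therefore noise-dominated, which is worth knowing in itself:
  it shows how little topological signal survives 22 subjects when true
  couplings are weak.
* `build_modular_covariance()` — the study emulator: a *connected caveman*
  covariance with five contiguous communities of 18 regions
  (equicorrelated blocks, within-community correlation ≈ 0.97) and one weak
  bridge pair between adjacent communities. Equicorrelated blocks stay
  positive definite at any correlation below 1, which is the only way to
  obtain structure strong enough to estimate reliably from 22 subjects. The
  resulting binarized networks have high clustering, short bridge-mediated
  paths, and clear betweenness bottlenecks — the modular variant of the
  small-world family. The near-redundant within-community correlation is an
  idealization: real metabolic covariance is weaker and more graded, so
  passing tests demonstrate that the chain recovers planted structure when
  it is estimable, not that 22 subjects suffice for real cohorts.

Planted alterations model hub pathology at the covariance level:
`strengthen` decouples a region from its own community and gives it
moderate covariance with six members of every other community, turning it
into a global bridge (its variance is raised to the minimal
positive-definite value, so its many cross-links are individually weak in
marginal correlation but highly ranked in partial correlation — high
betweenness without high pairwise r); `weaken` zeroes a region's
covariance; `pair_strengthen` couples two decoupled regions at correlation
0.967, the planted ground truth for seed-correlation recovery. Alteration
magnitudes were fixed once, by power calculation and simulation on seed
sets disjoint from the test suite's, so that planted-hub recovery has
roughly 80% per-seed power and seed-target recovery roughly 95%; they are
parameters, not estimates of any clinical effect.

Positive definiteness after planting is restored locally: an altered
region's variance is raised to its Schur-complement lower bound plus a
small margin. A global diagonal load is only a last-resort fallback — a
global repair dilutes every correlation in the matrix and silently destroys
the very contrast the alteration plants.

`make_toy_atlas()` partitions an ellipsoidal mask into contiguous regions
by nearest-seed (Voronoi) labelling from random in-mask seed voxels —
cells of a convex mask are convex, hence connected — and
`render_subject_volumes()` paints regional values onto the grid with
optional voxel noise so the voxel-level stages (smoothing, extraction,
seed correlation) are exercisable at desk scale (24³ grids).

## Numerical conventions and degenerate inputs

* Nodes with fewer than two neighbours contribute 0 to clustering and
  local efficiency; an edgeless graph has `L = Inf` and `E_glob = 0`.
* Distances come from level-synchronous BFS via boolean matrix powers —
  exact for these dense ≤ 90-node binary graphs and faster than per-node
  traversal in R.
* If every betweenness value is 0 (complete graphs), `bi` is returned as
  all zeros with a degeneracy flag rather than dividing by zero.
* `fisher_z` clips |r| ≥ 1 to ±(1 − 1e−7) with a warning; zero-variance
  voxels get r = 0 and are excluded from the FDR family.
* The two-sample comparison of Fisher-transformed correlations uses the
  square-root denominator `sqrt(1/(n1−3) + 1/(n2−3))` — the standard
  statistic; typeset sources sometimes drop the radical.
* Edge counts use `floor`, never rounding; all tie-breaks are
  lexicographic; every stochastic step takes an explicit seed and restores
  the caller's RNG state.
* Whole-brain normalization defaults to the mean/sd of the subject's
  region means, so the table path and the volume path of the pipeline
  agree exactly at zero rendering noise; voxel-weighted whole-brain
  statistics (`brain_stats = "voxels"`) are available when voxel-level
  fidelity matters more than cross-path equality.

## Problem sizes used by the shipped analyses

The numbered scripts under `analysis/` and the acceptance script run the
full study layout (2 × 22 subjects, 90 regions, 24³ volumes) with 200
rewired nulls, 500–1000 relabelings for inference stages, and 100–200
simulated datasets for calibration rates; these sizes give stable rates
while keeping each script in the minutes range on one CPU.

## Known limitations

* The generator emulates covariance structure, not PET physics: no
  attenuation, scanner resolution, partial-volume effects, or anatomical
  geometry; the toy atlas is an ellipsoid, not a brain.
* With 22 subjects per group, betweenness values of individual estimated
  networks remain noisy however strong the true structure; permutation
  p-values for single-region hub alterations should be read as screens,
  not confirmations.
* One-tailed metric-curve p-values are taken in the observed direction and
  reported with that direction; across a 35-point sparsity grid with no
  multiplicity correction (deliberately, matching the headline procedure),
  some p < 0.05 entries are expected by chance. An FDR switch is available
  for the curves but off by default.
* Only binary undirected networks are analysed; weighted and directed
  variants are out of scope.
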