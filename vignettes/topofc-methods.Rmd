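---
title: "Topological analysis of functional connectivity: models and methods"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Topological analysis of functional connectivity: models and methods}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(topofc)
```

## The problem

Mild cognitive impairment disturbs the coordination of resting-state brain
activity before it disturbs behaviour. `topofc` quantifies that disturbance
topologically: ROI-level fMRI time series are turned into filtered spaces
whose persistent homology — the births and deaths of connected components,
loops and voids across a scale parameter — summarises network organisation
in a way that is robust to monotone rescalings and insensitive to the exact
choice of threshold that plagues classical connectivity analyses.

Two complementary filtrations are implemented end to end.

**Vietoris–Rips arm.** Each ROI series \(f_1, \dots, f_N\) is delay-embedded,
\(t \mapsto (f(t), f(t+\tau), \dots, f(t+M\tau))\), with defaults \(M = 2\),
\(\tau = 1\): a sliding window of three consecutive samples, giving \(N - 2\)
points in \(\mathbb{R}^3\). The Vietoris–Rips filtration over the cloud (a
simplex enters when its largest pairwise distance reaches the scale) yields
persistence diagrams in dimensions 0–2. Diagrams of different ROIs are
compared with the q-Wasserstein distance, producing one ROI-by-ROI distance
matrix per subject and network; these matrices feed a hybrid
dense-plus-convolutional classifier.

**Graph-filtration arm.** Per subject and network, a weighted graph keeps an
edge exactly when both the Pearson (marginal) and the partial correlation of
the two ROIs are strictly positive — the two estimators must agree on a
positive association; the partial-correlation value is the default edge
weight because a vanishing partial correlation indicates the absence of a
direct connection. The filter assigns each edge its weight and each vertex
the minimum over its incident edges. Sublevel sweeps give the 0-th ordinary
diagram (component births and elder-rule deaths); the cone construction over
the combined sublevel/superlevel filtration gives the 1-st extended diagram,
one point per independent cycle with birth ≥ death. Subject-by-subject
Wasserstein matrices per network are tested for group differences with
Wilcoxon rank-sum tests and classified from top-lifespan features with a
stacked ensemble.

## The synthetic cohort model

No subject-level imaging data can ship with the package, so every analysis
is exercised on synthetic cohorts whose statistical structure matches what
the filtrations assume. The generator (`cohort_spec()`, `generate_cohort()`)
draws, per network, `latent_rank` (default 2) shared AR(1) drivers and sets
ROI \(i\) of a subject in group \(g\) to
\[
x_i(t) = \sqrt{c}\, m_i(t) + \sqrt{1 - c}\,\sigma\,\epsilon_i(t), \qquad
c = c_{\mathrm{base}} + \mathrm{shift}(g),
\]
with \(m_i\) a unit-variance non-negative mixture of the drivers and
\(\epsilon_i\) idiosyncratic AR(1) noise. Group effects enter through the
coupling \(c\) only — connectivity, not signal mean — because every
downstream analysis is connectivity-topological. Non-negative mixing weights
make within-network correlations lean positive, as resting-state networks do
and as the positive-graph construction requires.

Defaults and why:

* `networks`: the six-network parcellation (CB 18, CO 32, DMN 34, FP 21,
  OP 22, SM 33; 160 ROIs).
* `n_timepoints = 150`: within the 130–190 volume range typical of
  TR ≈ 3 s resting-state acquisitions after discarding initial volumes.
* `ar_coefficient = 0.4`: visibly band-limited series without near-unit-root
  pathology.
* `coupling_base = 0.3`, planted shift `+0.3` for the impaired group,
  20 subjects per group: the study conditions used by the calibration and
  recovery suites below.
* One master seed drives a per-subject seed sequence, so any subject can be
  regenerated individually and identical specs give bit-identical panels.

What the generator does **not** emulate: hemodynamics, motion and scanner
artifacts, spatial autocorrelation, inter-subject variability in network
membership, and any oscillatory (limit-cycle) dynamics. Passing tests
therefore demonstrate that the pipeline recovers planted *connectivity*
differences from data with fMRI-like second-order structure — not that it
reproduces published accuracies on real cohorts, which are out of reach
without the original data.

## Numerical choices

* **Rips reduction.** Boundary-matrix reduction over GF(2), blockwise per
  dimension, with simplices ordered by (filtration value, lexicographic
  vertex order). Edge inclusion is non-strict (distance ≤ scale); on a
  finite point set this differs from the strict convention only on a
  measure-zero set of scales and matches common practice. The default scale
  cap is the enclosing radius, past which no finite feature survives.
  Zero-persistence pairs are kept in dimension 0 — so H0 bar counts equal
  point counts — and dropped above. With `max_dim = 2` clouds are first
  reduced to 60 points by seeded farthest-point subsampling to keep
  3-simplex enumeration tractable; both cap and subsample are configurable.
* **Extended persistence.** Computed by reducing the cone of the
  sublevel/superlevel filtration. A tempting shortcut — pairing each
  independent cycle with the minimum edge value along the cycle its
  non-forest edge closes — is wrong whenever two cycles share their weakest
  edge: extended persistence assigns distinct death events. The randomized
  oracle suite (full cone reduction, written independently in the tests)
  guards this. Ties in edge values are broken by canonical vertex order,
  and a dedicated suite checks the diagram multiset is invariant under
  reordering of tied edges.
* **Partial correlation.** The precision matrix is taken from a
  Ledoit–Wolf-shrunk covariance (target: scaled identity, intensity from
  the standard closed form) because ROIs per network rival timepoints in
  number; `shrinkage = 0` recovers the textbook estimator and is what the
  regression-residual oracle tests use.
* **Wasserstein distance.** Each diagram is augmented with the diagonal
  projections of the other's points; matching costs are q-th powers of
  L∞ differences (a point's diagonal cost is half its persistence) and the
  optimum is found by an exact Jonker–Volgenant assignment solver. Essential
  points are truncated to the largest finite death of the compared pair by
  default (`drop_essential` is available); q defaults to 1. Empty-vs-empty
  is 0 by convention.
* **Wilcoxon tests.** Exact enumeration when the smaller sample has ≤ 10
  tie-free values, otherwise the normal approximation with continuity and
  tie corrections; fully tied data return p = 1. No multiplicity correction
  by default (summaries mirror per-network, per-dimension reporting);
  Benjamini–Hochberg is a flag.
* **Stacked ensemble.** Ten base classifiers are ranked by stratified
  5-fold CV accuracy on the 80% training split; the top five are stacked
  under a random-forest meta-model fed with out-of-fold probabilities.
  Gradient boosting, LightGBM and CatBoost are realised as xgboost variants
  with distinct hyperparameter profiles, and AdaBoost as SAMME boosting
  over decision stumps; the fitted object records these substitutions.
* **Hybrid network.** The conv branch (3×3 "same" convolutions, 16/32/64,
  one 2×2 max-pool, 128/256, global average pooling) and the flat branch
  (n² → 256 linear) concatenate into dense layers 128/64/32 with dropout
  0.2 and a 2-way softmax; cross-entropy loss, Adam or SGD, early stopping
  with patience 10 within a 100-epoch cap. Inputs are z-scored with
  training-set statistics — without this the five-layer conv stack
  saturates on raw distance magnitudes. A closed-form parameter count
  (`hybrid_net_param_count()`) guards the architecture, and analytic
  gradients are tested against finite differences. The hyperparameter
  search is a seeded random search over the configured grids (learning rate
  log-uniform on [1e-4, 1e-1], batch ∈ {4, 8, 16, 32}, split ∈
  {0.2, 0.25, 0.3}, optimizer ∈ {SGD, Adam}), with subjects split by ID at
  every stage.

## Design choices where the design was open

* **Which correlation supplies the positive graph's edge weight** is not
  determined by the construction itself; the package defaults to the
  partial value (the direct-connectivity estimator) with the marginal value
  selectable.
* **Filter direction.** `identity` (weak edges enter the sublevel sweep
  first) is the stated rule and the default; `one_minus_w` is provided for
  users who want strong correlations early. Neither is asserted as the
  published setting.
* **Wilcoxon sample assembly.** The default `within_block_upper_triangle`
  policy compares the two groups' within-group distance blocks — the
  natural reading of testing "distributions of inter-subject distances" —
  but its entries share subjects and are therefore dependent: simulation
  shows the nominal 5% test rejecting a true null about half the time at
  these sample sizes. The alternative `mean_distance_per_subject` policy
  (one value per subject) is calibrated (measured null rejection 3–5% at
  α = 0.05). Consequently the package's null-calibration suite runs the
  per-subject policy, while the power suite exercises the default
  within-block policy at the planted effect, where it rejects in ≥ 90% of
  seeds. Users testing real data should prefer the per-subject policy or a
  permutation scheme.
* **Essential points in distances and lifespans** default to truncation and
  exclusion respectively, both configurable.

## Problem sizes used by the shipped suites

The calibration and recovery suites run on reduced cohorts chosen so that
exact assignment solves and cone reductions remain desk-scale: a single
network of 10–12 ROIs, 100–150 timepoints, 10–20 subjects per group, 200
seeds for the null size, 100 for power, 20 for ensemble recovery and 10 for
the hybrid classifier. The planted effect itself (coupling shift +0.3,
20 subjects per group) follows the generator defaults. With these sizes the
measured behaviour is: null rejection within the 99% binomial band of
α = 0.05; power ≥ 0.8 for both homology dimensions; ensemble held-out
accuracy ≈ 0.89 averaged over seeds against a chance level of 0.5.

## Known limitations

* The subject-specific inter-ROI Wasserstein matrices of the Vietoris–Rips
  arm respond to the generator's coupling shift only weakly: every ROI has
  the same marginal process, so coupling changes shrink the sampling
  variability between two ROIs' diagrams rather than moving their
  expectations apart. Planted-structure recovery for the hybrid classifier
  is therefore demonstrated on distance matrices with an explicit block
  effect; on real data, where regions differ in their dynamics, the
  inter-ROI matrices carry richer structure than this generator produces.
* Extended persistence is limited to dimension 1 — on a graph (a
  1-complex) no higher-dimensional extended classes exist.
* The exact assignment solver is O((m+n)³) per diagram pair; networks of
  hundreds of ROIs per network would need an approximate transport backend
  that the package deliberately does not include.
* All classifiers are binary, mirroring pairwise group contrasts; no
  multi-class extension is provided.
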