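---
title: "Autoencoder-filtered gene selection with Shapley attribution: methods and design"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Autoencoder-filtered gene selection with Shapley attribution: methods and design}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dsafgs)
```

## The problem

Genome-scale expression cohorts pair tens of thousands of gene measurements
with a few hundred patients and a binary clinical endpoint (here generically
"event": therapy need or death within follow-up). Three obstacles dominate:
the curse of dimensionality, class imbalance, and heavy redundancy — probes
and co-regulated transcripts measure nearly the same signal many times over.
`dsafgs` implements a hybrid feature-selection pipeline that removes
redundancy *without leaving the original feature space* (every retained
feature is a real gene, not a latent projection), then attributes a trained
classifier's predictions back to individual genes:

1. **Correlation.** The gene–gene Pearson matrix is computed across
   patients, in row blocks whose results are identical to the dense
   computation.
2. **Clustering.** Genes are cut into *k* clusters (default 500) by
   average-linkage hierarchical clustering on the dissimilarity `1 − r`.
3. **Autoencoder filter.** For each cluster, an autoencoder is trained on
   the transposed sub-matrix (patients as features, genes as samples); the
   cluster's *representative* is the member gene with the lowest mean
   absolute reconstruction error. This collapses each redundancy block to
   its most prototypical member.
4. **Supervised ranking.** Representatives are ranked by the one-way
   F statistic (between- over within-class mean squares; for two groups,
   the square of the pooled t statistic) and truncated to candidate subset
   sizes (default 5, 10, 50, 100, 300).
5. **Classifier and model selection.** For each subset size, a grid of
   feed-forward networks (2/3/4 hidden layers; first widths 8–256 with
   floor-halving; relu; single sigmoid output; binary cross-entropy; Adam
   at 0.001) is evaluated by Monte-Carlo cross-validation: 10 stratified
   random 90/10 splits, SMOTE applied to the training portion only. The
   chosen configuration maximizes mean test accuracy; the returned model
   is its best iteration.
6. **Attribution.** Kernel SHAP — weighted least squares over coalition
   indicators under the Shapley kernel `(m−1)/(C(m,s)·s·(m−s))` — explains
   the chosen model's sigmoid score against a seeded 100-patient
   background; genes are ranked by mean |φ|.

## Model assumptions

- Expression values are log-scale intensities on comparable scales across
  patients; the pipeline performs no normalization of its own.
- Redundancy is well approximated by linear correlation; anticorrelated
  genes are treated as distinct signals (dissimilarity `1 − r`; an
  `1 − |r|` option exists for magnitude-based grouping).
- A cluster is only meaningfully summarized by one representative when its
  members are strongly interchangeable; for loosely correlated clusters the
  representative discards real information. This matters for interpreting
  the synthetic benchmarks below.
- The F ranking is a marginal filter: genes informative only through
  interactions can be lost between steps 4 and 5.

## Parameters that matter

| Parameter | Default | Meaning |
|---|---|---|
| `k_clusters` | 500 | number of redundancy blocks retained |
| AE layers | P, ⌊P/5⌋, ⌊P/10⌋, ⌊P/5⌋, P | symmetric bottleneck per cluster; P = 217 gives 217-43-21-43-217 |
| AE training | relu, Adam lr 0.01, MAE, 1000 epochs | reconstruction objective per cluster |
| `subset_sizes` | 5, 10, 50, 100, 300 | candidate top-k gene panels |
| grid | depths {2,3,4} × first widths {8,…,256} | 18 classifier architectures, halving widths |
| cv | 10 × 90/10 stratified | Monte-Carlo cross-validation |
| SMOTE | k = 5 neighbors, training folds only | class balancing; synthetics never reach a test set |
| SHAP background | 100 patients | reference sample for the interventional expectation |

All of these sit in one `run_config()` object; the defaults reproduce the
reference protocol exactly.

## Numerical and design choices

Points the protocol leaves open were fixed as follows; each is a package
design choice, testable in isolation.

- **Feed-forward core.** Both the autoencoders and the classifier run on a
  single dense-network implementation (He initialization, mini-batch Adam,
  exact MAE subgradient with `sign(0) = 0`, combined sigmoid/cross-entropy
  output delta). Training is bitwise deterministic for a fixed seed; every
  stage derives independent sub-seeds from the master seed, so any stage
  can be replayed in isolation.
- **AE input scaling.** Per-patient standardization inside a cluster
  sub-matrix is available but **off by default**: the cluster's genes are
  the training samples, so per-feature centering subtracts the cluster's
  shared expression pattern — precisely the signal the autoencoder must
  learn — and demonstrably degrades representative recovery.
- **Ties.** Minimum reconstruction error, equal F values, equal mean cv
  accuracy (fewer parameters first, then enumeration order), equal
  iteration accuracy (lowest index), and equal mean |φ| (lexicographic
  gene id) are all broken deterministically.
- **Zero-variance genes** have undefined correlation; their off-diagonal
  entries become 0 with a warning (configurable hard error). A
  zero within-class sum of squares with unequal means yields an `Inf`
  F sentinel that sorts above every finite value.
- **Test-set sizing.** `round_half_up(n_class × 0.10)` per class:
  217 patients split 120/97 give 12 + 10 = 22 test samples per iteration.
  Stratification avoids degenerate single-class test sets at this size.
- **Linear-limit oracle.** With linear activations and squared error, a
  bottleneck-*b* autoencoder converges to the affine rank-*b* fit (column
  mean plus truncated SVD of the centered matrix); the package ships that
  closed form and tests selection against it. The production path (relu,
  MAE) is validated separately on clusters with a known prototype.
- **Kernel SHAP solve.** The efficiency constraint Σφ = f(x) − base is
  eliminated exactly (never merely penalized); all 2^m − 2 coalitions are
  enumerated for m ≤ 15, where the weighted regression recovers exact
  Shapley values; larger m uses a deterministic seeded design (complete
  outer coalition sizes first, residual budget sampled by kernel mass,
  duplicates removed with analytic weights). A singular design falls back
  to a tiny ridge with a warning.
- **Explained set.** Mean-|φ| importance is computed over the background
  subsample itself by default (the explained patients and the reference
  distribution coincide); any patient set can be passed explicitly.

## What the synthetic generator emulates — and what it does not

`synthetic_spec()` defaults describe a cohort shaped like the reference
study: 19,367 genes × 217 patients, class split 120/97, 500 blocks. Genes
follow a latent-factor block model (`sqrt(r)·factor + sqrt(1−r)·noise`),
giving within-block correlation ≈ `within_cluster_r` and ≈ 0 between
blocks.

Label signal is planted as *outcome-associated modules with a hub gene*:
in each informative block the factor receives the class shift, and the
planted gene is the block's hub — loading 1, no idiosyncratic noise — so
it separates the classes by exactly `effect_size` within-class standard
deviations and is the member an autoencoder reconstructs best. This is the
realistic analogue of a tightly co-regulated outcome-associated module
whose cleanest member should survive redundancy removal. A `confound` flag
instead co-locates all planted genes in one block as ordinary members, the
stress case where redundancy removal must discard most of them.

`within_cluster_r` defaults to 0.9. The choice is deliberate: the
autoencoder filter is a redundancy remover, and 0.9 models blocks of
near-interchangeable measurements (duplicate probes, tight co-regulation).
At markedly lower correlation the members of a block are *not* redundant;
reconstruction error then separates genes mostly by their idiosyncratic
noise — which the per-cluster autoencoder (bottleneck ⌊P/10⌋, roughly half
a typical cluster's size) can partially memorize — and no argmin-style
selector can single out a representative reliably. Passing tests on this
generator therefore demonstrate correct mechanics and recoverability in
the redundancy regime the method targets; they do not certify performance
on weakly correlated real modules, batch effects, probe-level artifacts,
or non-Gaussian noise, none of which the generator emulates. Survival
endpoints are out of scope throughout.

## Problem sizes used in the shipped checks

The test suite exercises the full pipeline at reduced, fixed scales chosen
as representative desk-scale problems: end-to-end recovery on 2,000 genes
× 200 patients (110/90), 10 planted hubs at effect 1.5 sd, 50 clusters,
200 autoencoder epochs, subset sizes {20, 50}, a 4-configuration grid
(depths {2, 3} × first widths {16, 64}, 150 epochs), and a 768-coalition
SHAP budget over a 100-patient background; determinism and null-behavior
checks run on smaller cohorts (300–500 genes). The null check verifies
that with `effect_size = 0` the chosen model's mean cv accuracy stays in
the chance band — the canary for SMOTE or selection leakage into test
sets. The acceptance script (`scripts/acceptance.R`) re-runs the same
computations from scratch at these scales.

## Known limitations

- The per-cluster autoencoder has substantial capacity relative to typical
  cluster sizes (≈ 39 genes per cluster at the default k; bottleneck 21 at
  P = 217). Long training can partially memorize individual noisy genes,
  which blurs representative choice in weakly correlated clusters — see
  the generator discussion above.
- Monte-Carlo accuracy intervals (mean ± 1.96 sd over 10 iterations) treat
  iteration accuracies as independent; overlapping training sets make them
  optimistic.
- Kernel SHAP beyond m = 15 features is an estimate whose precision is set
  by the coalition budget; efficiency holds exactly by construction, but
  individual φ's carry sampling error.
- A printed confusion matrix implying more test samples than a 10% split
  provides (e.g. 44 versus 22) cannot arise from a single iteration under
  this protocol; `confusion_from_rates()` checks internal consistency of
  such published counts but cannot resolve their provenance.
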