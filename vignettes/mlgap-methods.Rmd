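---
title: "Methods: models, parameters and design choices in mlgap"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: models, parameters and design choices in mlgap}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the statistical machinery inside `mlgap`, the
defaults it ships with, and the places where the design was genuinely
open and a choice had to be made. It states no empirical result beyond
what the package's test suite and `scripts/acceptance.R` themselves
compute.

## The count model and the simulator

The package targets bulk RNA-seq read counts: a genes × samples integer
matrix in which gene *i* in sample *j* is modelled as negative binomial
with mean μ<sub>ij</sub> and dispersion φ, so that
Var = μ + φμ². The bundled simulator (`simulate_study()`) draws

* per-gene baseline means from a gamma distribution rescaled into
  `base_mean_range` (default 5–500), giving the strong mean–variance
  dependence a variance-stabilizing transform has to remove;
* per-sample library-size factors ℓ<sub>j</sub> from a log-normal with
  median 1 and σ = `libsize_sigma` (default 0.25, a realistic spread of
  sequencing depths), so size-factor estimation has non-trivial work to
  do and its accuracy is testable against the known truth;
* a planted set of `n_deg` differential genes, half up-regulated by
  2^`log2fc` in class 1 and half down-regulated by 2^−`log2fc`, so
  volcano plots have both wings and recovery can be scored against
  ground truth;
* counts `rnbinom(mu, size = 1/φ)`, or Poisson in the φ = 0 limit.

The simulator reproduces the *shape* of a two-class tumour cohort
(class imbalance, depth variation, a minority of truly differential
genes). It deliberately omits gene–gene correlation, batch effects and
multi-class structure: a pipeline that passes its tests has been shown
to work under independent-gene NB sampling, not under every artefact of
real cohorts.

## Filtering

`filter_genes()` removes genes with a row sum below `min_total`
(default 10, a common low-count floor), then zero-variance genes, and
genes that are near-zero-variance: most-common/second-most-common value
frequency ratio above 19 **and** fewer than 10% distinct values. The
19/10 pair is the long-standing default of the near-zero-variance
practice in predictive-modelling toolkits; the thresholds are exposed
because shallow cohorts may need gentler settings.

## Size factors: two conventions

`compute_size_factors()` implements median-of-ratios with an explicit
convention switch. With G<sub>i</sub> the geometric mean of gene *i*
across samples (zero as soon as any count is zero) and m<sub>j</sub> the
per-sample median of x<sub>ij</sub>/G<sub>i</sub> over genes with
G<sub>i</sub> ≠ 0:

* `mode = "unit_sum"` (default): s<sub>j</sub> = m<sub>j</sub> / Σ<sub>j</sub>
  m<sub>j</sub>, so the factors sum to exactly 1;
* `mode = "deseq"`: s<sub>j</sub> = m<sub>j</sub>, the classical
  median-of-ratios estimator.

The renormalized form divides all counts by a common constant relative
to the classical one. Every downstream computation in this package —
dispersion-trend fitting, VST, rank-based gene selection, classifier
features — is invariant to a global rescaling of the normalized matrix,
so the choice is a matter of convention, not of results; both are kept
because both conventions circulate. Medians over an even number of
ratios are the arithmetic mean of the two central order statistics;
the test suite pins this against a brute-force loop oracle to 1e-12 and
against `DESeq2::estimateSizeFactorsForMatrix` (which interpolates even
medians in log space, hence the cross-check uses an odd gene count).

## The variance-stabilizing transform

Rather than delegating to an external VST, the package fits the
two-parameter dispersion trend φ(μ) ≈ a₀ + a₁/μ by least squares on
method-of-moments dispersions φᵢ = max(0, (varᵢ − meanᵢ)/meanᵢ²), using
only genes with mean > 1 because moment dispersions explode at tiny
means. The closed-form transform for that trend,

v(q) = log₂[(1 + a₁ + 2a₀q + 2√(a₀q(1 + a₁ + a₀q))) / 4a₀],

is strictly increasing and asymptotically log₂(q) + constant. It is
deterministic, analytically testable (the suite checks a hand-evaluated
point, monotonicity, and a ≥10× reduction of the SD-versus-mean slope on
NB data), and degrades gracefully: if the fitted a₀ is non-positive
(e.g. Poisson data with no overdispersion) the transform falls back to
log₂(q + 1) and flags `fallback_used`. A fitted negative a₁ is clamped
to 0 — at that point the trend is flat and the low-mean term has no
support in the data.

## PCA screening and DEG selection

"Reducing genes by PCA" is ambiguous, since PCA produces components,
not genes. `pca_gene_screen()` keeps *genes*: each gene is scored by its
variance-weighted loading energy Σ<sub>c≤C</sub> λ<sub>c</sub>
w<sub>gc</sub>², where C is the smallest number of components reaching
`var_target` (default 0.90) cumulative variance, capped at
min(n−1, 50). This preserves gene identity for the explainability stage
— latent components cannot be looked up in a pathway database. Genes are
standardized first; zero-variance genes score 0. Ties break by gene id,
so the screen is a deterministic function of the data.

The DE stage is a per-gene Welch two-sample *t* test on VST values with
Welch–Satterthwaite degrees of freedom and Benjamini–Hochberg
correction. The Welch form was chosen over the pooled-variance *t*
because equality of group variances across tumour subtypes is exactly
the kind of assumption one cannot make; a count-model Wald/LRT test was
deliberately not used because after VST the values are approximately
Gaussian and a transparent test keeps the selection auditable. The
log2 fold change is the VST-scale mean difference (class 1 − class 0).
Selection takes a fixed number of genes (`n_deg`, default 200) by rank
— ascending p, ties by |log2fc| then gene id — rather than an FDR
cutoff, because downstream arms need a fixed feature dimension.

## The autoencoder arm

The default architecture is 200 → 128 → 72 → 128 → 200 with rectifier
hidden layers and a linear output, trained on the mean-squared
reconstruction error of per-feature standardized inputs by minibatch
Adam (epochs 200, batch 32, learning rate 1e-3 — standard stable
settings, all configurable). The scaler is fitted on the training split
only, so no test-set statistics leak into the representation. The
trainer is implemented in base matrix algebra inside the package; at
these layer widths (tens to hundreds of units) a dedicated deep-learning
backend buys nothing, and a self-contained trainer makes seeded runs
bitwise-reproducible, which the test suite asserts.

One wrinkle is documented rather than resolved: descriptions of this
architecture circulate with both 72 and 63 as the latent width.
`bottleneck_dim` defaults to 72 (the explicitly specified layer) and is
configurable; nothing in the package depends on the specific value. The
"72 best-reconstructed test observations" reading is exposed separately
as `reconstruction_errors()` + `top_k()` — a reporting device — while
the classification arm always consumes the latent features from
`encode()`.

## MixUp augmentation

`mixup_augment()` implements x̃ = λxᵢ + (1−λ)xⱼ with λ ~ Beta(α, α),
α defaulting to 0.2 (a conventional mixing intensity; small α keeps
synthetic rows near one parent). Pairing is strictly within class, so
ỹ = λyᵢ + (1−λ)yⱼ collapses to the common parent label exactly and the
tree ensembles downstream keep training on hard labels. Two modes
exist because two descriptions of the procedure circulate:
`minority_only` synthesizes minority rows until the classes balance
(the stated motivation — class imbalance), while `full_double`
(default) adds exactly n synthetic rows drawn proportionally to class
frequencies, doubling the dataset (the arithmetic that matches the
published dataset shapes, 1128 → 2256 and 929 → 1858). In
`run_pipeline()` augmentation touches the training split only; the test
split is never augmented, so reported metrics are computed on real
samples exclusively.

## Split, grids and metrics

The 80/20 split is stratified (proportions preserved within one sample
per class) — a plain random split can starve a small class in the test
set. Grid search is exhaustive over small default grids (forest:
trees {200, 500} × depth {unlimited, 10}; boosting: 200 rounds ×
depth {3, 6} × learning rate {0.1, 0.3}) with stratified 5-fold CV
scored by accuracy; ties resolve to the earlier grid row. The six
metrics (accuracy, PPV, NPV, sensitivity, specificity, F1) come from
the confusion counts; any zero-denominator ratio is reported as `NaN`
with a flag, never silently as 0. The positive class defaults to the
lexicographically larger label and is overridable — with two arbitrary
subtype labels there is no natural "positive", and the swap symmetry
(precision↔NPV, recall↔specificity) is property-tested.

## Explainability and consensus

Three rankings are computed on the best arm/model (highest test
accuracy; ties prefer the MixUp arm, then boosting):

* **varimp** — the model's own impurity-decrease (forest) or split-gain
  (boosting) importance, normalized to sum 1;
* **SHAP** — exact tree-path-dependent SHAP values via the boosting
  library's prediction-contribution mode (local accuracy holds to
  float precision, asserted in the tests); forests use an in-package
  Monte-Carlo permutation-sampling Shapley estimator (unbiased, with
  variance shrinking as 1/√n_mc);
* **LIME** — per explained sample, Gaussian perturbations (per-feature
  scale from the explained set), an exponential kernel on standardized
  distance with width 0.75√p, and a weighted lasso surrogate read at
  the sparsest path point with at most 10 active features.

Attribution scores are aggregated as the mean absolute value over the
whole test set — the least arbitrary choice when no explicit subset is
specified. The consensus keeps features present in at least
`min_methods = 2` of the three top-`k = 10` lists and tabulates the
seven Venn regions. All rankings break ties by feature id, making the
entire explanation stage deterministic under a seed.

## Volcano reporting

Genes split into three exclusive categories: `significant`
(p < 0.05 and |log2fc| ≥ 1, the boundary counting as significant),
`non_significant` (p < 0.05, small fold change) and `unregulated`
(p ≥ 0.05 — the gray zone). The thresholds are conventional volcano
defaults and configurable, including thresholding adjusted p instead.
`check_consensus_not_gray()` verifies that no consensus feature is
unregulated — influential-but-not-differential features would signal a
selection artifact. When the best arm is the autoencoder the consensus
names latent dimensions, not genes, and the check is recorded as not
applicable.

## Problem sizes and numerical tolerances in the tests

The suite exercises the statistics at sizes where Monte-Carlo noise is
controlled but runtimes stay in seconds: moment checks on 200–300 genes
× 240–300 samples (3·SE bands), null calibration and slope-reduction
checks on 2,000–2,500 genes, recovery experiments on 2,000 genes with
20 planted DEGs at log2FC 2, and end-to-end pipeline runs on 600 genes
× 100 samples. The size-factor oracle comparison is exact to 1e-12;
SHAP local accuracy is asserted at 1e-5 (the trees accumulate in single
precision); autoencoder determinism is bitwise because the trainer is
pure R.

## Known limitations

* Independent-gene simulation: co-expression, batch structure and
  outlier samples are not emulated, so passing tests bound behaviour
  under the NB model only.
* The dispersion trend is a two-parameter least-squares fit, not a
  shrinkage estimator; very small cohorts (< 50 genes after filtering
  triggers a warning) give noisy (a₀, a₁).
* The sampling Shapley estimator for forests is stochastic; its
  rankings stabilize with `n_mc` but individual attributions carry
  Monte-Carlo error, unlike the exact boosting path.
* Two-class contrasts only, by design.
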