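---
title: "Differential gene-pair networks: model, choices and limitations"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Differential gene-pair networks: model, choices and limitations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(jdinac)
```

## The estimation problem

Two diagnostic groups — cases and controls — are assumed to differ through
the *joint* behaviour of gene pairs rather than (or in addition to) single-gene
means. For genes `G_i, G_j`, write `f¹_ij` and `f⁰_ij` for the bivariate
densities of `(G_i, G_j)` within class 1 and class 0. A pair is
*differential* when these densities differ, which covers changes in
correlation, in nonlinear association, or in joint location, without any
parametric model of either density. The classifier is a logistic
regression on the per-sample evaluations of `ln(f¹_ij / f⁰_ij)` across all
pairs, with an L1 penalty on the pair coefficients and demographic
covariates (age, sex, years of education) entering unpenalized so that
group differences explainable by demographics are absorbed before any pair
is selected.

The same data cannot both estimate the densities and fit the regression
without optimism, so each of `H` rounds splits the training samples
(stratified by class, 50/50) into a *density part* and a *model part*.
Prediction averages the `H` per-split probabilities; selection stability is
summarized by the weight `w_ij`, the number of rounds in which
`β̂_ij ≠ 0`. Pairs with `w_ij ≥ 1` (default) form the edges of the
differential network; genes with at least five neighbours are reported as
hubs, ordered by total incident weight (ties broken alphabetically — the
alternative ordering by coefficient magnitude is also computed in
`tidy()` output as `mean_abs_coef`).

## Assumptions

* Expression values are continuous and per-sample rows are exchangeable
  within class. No distributional form is assumed for the densities.
* The covariates act additively on the logit scale. Confounding that
  interacts with gene pairs is not modelled.
* Density estimates from roughly half the training class sizes (here,
  dozens of samples per class) are informative at the smoothness of
  typical expression data. With fewer than ~10 samples per class per
  split the ratio features become noisy and weights lose meaning.

## Tunable parameters

| Parameter | Default | Meaning and rationale |
|---|---|---|
| `n_splits` (H) | 20 | Number of split/fit rounds. Weights stabilize around 20 at these sample sizes; doubling H roughly halves the Monte-Carlo variance of weights at double cost. |
| `swap_roles` | `TRUE` | Uses each random partition in both (density, model) orientations, so H fits need only H/2 partitions; a free variance reduction. H must then be even. |
| Bandwidths | normal-reference | `h = 1.06 · min(sd, IQR/1.34) · n^(−1/5)` per axis, per class, floored at 1e−6; `bandwidth_scale` multiplies both. Standard, robust; the product-Gaussian kernel keeps pairwise ratios simple. |
| `density_floor` | 1e−10 | Both densities are floored before the log so features stay finite far outside the training cloud; a true zero density would otherwise produce ±∞ and break the linear model. |
| `cv_folds` | 5 | Stratified folds; λ chosen at minimum mean binomial deviance (`lambda.min`, not 1-SE) because the workflow is prediction-oriented. |
| `coef_tol` | 1e−8 | |β̂| below this counts as zero when computing weights, absorbing solver noise. |
| `min_weight` | 1 | Network edge threshold: any selection across splits creates an edge. Raising it can only remove edges; the value used is recorded in the JSON report. |
| `min_degree` | 5 | Hub definition: at least five adjacent genes. |
| `threshold` | 0.5 | Probability cutoff for accuracy/sensitivity/specificity/precision on the averaged probability. |
| `n_boot` | 2000 | Stratified percentile-bootstrap resamples for 95% CIs (resampling within class, preserving class counts). Percentile rather than BCa: simplest interval consistent with the bootstrap; note the point estimate is not guaranteed to lie inside a percentile interval. |

The zero-expression gene filter removes a gene when its fraction of exact
zeros is *strictly greater* than 30% (a gene at exactly 30.0% is kept);
the boundary convention follows the strict inequality in the filter's
definition. No normalization or transformation is applied by default —
`transform_expression()` offers `log2p1` and `zscore` for raw counts, and
the choice is recorded rather than guessed.

## What the generator emulates — and what it does not

`simulate_dataset()` draws each class from a multivariate normal whose
correlation matrix embeds a class-specific correlation for every planted
pair and a common background elsewhere (repaired to the nearest
positive-definite correlation matrix when a configuration is slightly
inconsistent; an irreparable configuration errors). Marginal mean shifts,
class-dependent demographic covariates (defaults match an elderly autopsy
cohort: age at death ≈ 88.3 (3.1) vs 84.6 (5.3), female fraction 0.689 vs
0.599, education ≈ 16.5 (3.4) years), and per-gene zero-inflation are
applied afterwards, in that order, so the planted correlations stay
interpretable. A `nonlinear` flag replaces the linear dependence of a
planted pair in class 1 by a quadratic one (partner driven by the squared
driver, near-zero linear correlation), exercising the nonparametric
estimator where correlation-based methods fail.

Gaussianity of the generator does **not** trivialize the method under
test, because the density-ratio estimator is nonparametric and never sees
the generating family. What the generator deliberately does *not*
reproduce: RNA-seq count marginals (negative binomial dispersion,
library-size variation), gene-gene correlation beyond the planted/background
structure, batch effects, and covariates that interact with expression.
Passing tests therefore demonstrate correct recovery of planted dependence
structure under realistic sample sizes — not performance on any particular
real cohort.

## Numerical choices and degenerate inputs

* KDE evaluation is an exact kernel sum (no grid interpolation): pair
  dimensionality is 2 and n is in the hundreds, so exactness costs little
  and avoids interpolation bias. Per-gene, per-class kernel matrices are
  shared across all pairs touching a gene; the result is identical (to
  1e−12 relative, tested) to fitting each pair independently.
* A zero-variance axis (e.g. an all-zero gene in one class) floors the
  bandwidth at 1e−6 with a warning, yielding a density spike rather than
  an error.
* Ranking ties: pairs with equal weight are ordered by mean |β̂| across
  selecting splits, then lexicographically; equal-weight hubs are ordered
  alphabetically. All orderings are deterministic.
* λ → ∞ (or no varying feature column) collapses the fit to the exact
  unpenalized covariate-only GLM — tested against `glm()` to 1e−4.
* A CV fold that must contain a single class errors immediately. A very
  small fold can also be quasi-separated by the unpenalized covariates,
  which makes the solver's path fit diverge; the fit then redraws folds
  (deterministically from the seed) and, as a last resort, falls back to
  the covariate-only model with a warning.
* Every random operation derives its seed from one global seed, namespaced
  by stage name, so adding a pipeline stage never changes the randomness
  of earlier stages, and identical configurations reproduce byte-identical
  artifacts.

## Open design points, resolved

* **H, split ratio, CV rule** are not canonical; H = 20, 50/50 stratified
  splits and `lambda.min` were fixed once as prediction-oriented defaults
  and are all config-exposed.
* **Test-set prediction** uses the averaged split models, not a refit on
  the full training set — consistent with treating the split ensemble as
  the estimator.
* **Baseline covariates**: the RF/PLR single-gene baselines exclude
  demographic covariates by default so they represent "individual genes
  only"; a flag adds them.
* **Cohort table statistics**: binary covariates use the Pearson
  chi-square without continuity correction (the correction materially
  changes borderline p-values, e.g. 0.072 → 0.09 on a 365-subject sex
  table); continuous covariates default to the unequal-variance t-test
  with the pooled variant available. Neither variant is claimed to match
  any externally reported education p-value exactly, since printed
  summaries round the inputs.

## Benchmark scale

The packaged benchmark (`pairwise_signal_benchmark()`) uses 30 genes
(435 pairs), 8 gene-disjoint planted pairs moving from correlation 0 to
0.8, zero marginal effects, class-independent covariates, 300 samples per
class split 2:1 train/test, and H = 20 — a desk-scale configuration that a
single CPU completes in well under a minute. The full-scale universe
(158 genes → 12 403 pairs) is supported by the same code path; cost grows
linearly in the number of pairs and in H.

On this benchmark the pairwise classifier reaches test AUCs around
0.92–0.98 across seeds while the penalized single-gene baseline stays near
chance, and all 8 planted pairs occupy the top 8 weight ranks. One
instructive observation, computed by the test suite and the
reproducibility script rather than asserted from theory: the random-forest
baseline is *not* at chance on dependence-only data (test AUC ≈ 0.69–0.75).
Axis-aligned recursive splits on the two genes of a correlated pair
partially capture their joint structure even when both marginals are
identical across classes — so RF is better described as weakly
interaction-sensitive than as a purely marginal method. The pairwise
density-ratio classifier still dominates it decisively (AUC gap ≥ 0.2,
DeLong p < 0.001 on every seed tried).

## Known limitations

* Only pairwise interactions are modelled; higher-order (3+ gene) joint
  structure is out of scope.
* Selection weights are stability scores, not inferential quantities: no
  per-edge p-values are provided, and the edge threshold is a reporting
  choice.
* The density-part/model-part split halves the effective sample size of
  each stage; with very small cohorts the variance of the ratio features
  dominates.
* Probabilities are averaged across splits without recalibration;
  threshold-based metrics inherit any miscalibration.
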