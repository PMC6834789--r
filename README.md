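# jdinac

Differential gene co-expression analysis and classification from **pairwise
gene interactions**, with an application profile aimed at case/control
transcriptomic cohorts such as Alzheimer's disease (AD) versus cognitively
normal controls.

Most expression classifiers rank individual genes. But in complex disease,
much of the signal lives in how *pairs* of genes co-vary — associations
that weaken, vanish, or appear as disease develops — and those changes are
invisible to marginal, single-gene statistics. This package implements a
joint density-based nonparametric differential interaction network analysis
and classification (JDINAC) workflow: it detects gene pairs whose joint
dependence differs between two diagnostic groups, assembles them into a
weighted differential network with hub genes, and uses them to classify
samples while adjusting for demographic confounders.

## The model

Let `X` be an `n × p` expression matrix, `Y_s ∈ {0, 1}` the diagnosis of
sample `s` (1 = case), and `Z_1 … Z_T` covariates (age, sex, education).
For every gene pair `(G_i, G_j)` the class-conditional joint densities
`f¹_ij` and `f⁰_ij` are estimated with a bivariate Gaussian product-kernel
KDE (normal-reference bandwidths, exact kernel-sum evaluation), and the
log-density-ratio `ln f¹_ij(G_i, G_j) / f⁰_ij(G_i, G_j)` becomes a
per-sample feature in a sparse logistic regression:

    logit P(Y = 1) = α₀ + Σ_t α_t Z_t + Σ_{i<j} β_ij ln( f¹_ij / f⁰_ij ),
    with an L1 constraint on Σ |β_ij| — covariates and intercept unpenalized.

Estimation uses repeated stratified sample splitting: each of `H` splits
uses half the training data to fit the densities and the other half to fit
the penalized model (penalty chosen by cross-validated deviance).
Predictions average the per-split probabilities; the **selection weight**
`w_ij` — the number of splits in which `β̂_ij ≠ 0` — ranks differential
pairs, defines the network edges, and identifies hub genes (≥ 5
neighbours). Single-gene random forest and penalized logistic regression
baselines, Mann–Whitney AUC, stratified bootstrap confidence intervals and
the DeLong test for correlated AUCs complete the evaluation suite.

## Worked example

```r
library(jdinac)

# two-class data in which genes 1-2 and 3-4 are uncorrelated in controls
# but correlated (rho = 0.8) in cases; no single-gene mean differences
sim <- simulate_dataset(
  n_class0 = 150, n_class1 = 150, n_genes = 10,
  planted_pairs = planted_pairs(c(1, 3), c(2, 4), rho0 = 0, rho1 = 0.8),
  seed = 42
)
plan <- stratified_split(sim$phenotype, n_train_pos = 100, n_train_neg = 100, seed = 42)
train <- sim$expression$sample_id %in% train_ids(plan)

fit <- jdinac(sim$expression[train, ], sim$phenotype,
  covariate_cols = c("age", "sex", "educ"), n_splits = 10, seed = 42)
head(tidy(fit), 4)
#> # A tibble: 4 × 4
#>   gene_a gene_b weight mean_abs_coef
#>   <chr>  <chr>   <int>         <dbl>
#> 1 G003   G004        9        0.295
#> 2 G001   G002        7        0.274
#> 3 G007   G010        4        0.0276
#> 4 G006   G007        3        0.290
```

Both planted pairs head the ranking: they were selected in 9/10 and 7/10
splits, while the best null pair reaches 4. Held-out classification and the
differential network:

```r
preds  <- predict(fit, sim$expression[!train, ], pheno = sim$phenotype)
report <- evaluate_predictions(list(jdinac = preds), sim$phenotype,
                               n_boot = 500, seed = 42)
dplyr::filter(tidy(report), metric %in% c("auc", "accuracy"))
#>   method metric   estimate ci_low ci_high
#> 1 jdinac auc         0.792  0.697   0.875
#> 2 jdinac accuracy    0.7    0.62    0.78

build_network(fit, min_weight = 5)
#> differential network: 2 edges over 4 genes (min weight 5)
#>   gene_a gene_b weight
#> 1 G003   G004        9
#> 2 G001   G002        7
```

An AUC of 0.79 from dependence alone — with zero marginal signal — is the
package's core point: `hub_genes()`, `top_pairs()` and
`autoplot()` methods explore the result further, `fit_baseline()` fits the
RF/PLR single-gene comparators, and `run_pipeline()` orchestrates the whole
workflow from a YAML/JSON config.

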