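test_that("huge lambda reduces the fit to the unpenalized covariate-only model", {
  set.seed(1)
  n <- 80
  y <- rep(0:1, each = 40)
  z <- tibble::tibble(age = rnorm(n, 80, 5), sex = rbinom(n, 1, 0.5))
  feats <- matrix(rnorm(n * 6), n, dimnames = list(NULL, paste0("p", 1:6)))
  fit <- fit_penalized_logistic(feats, y,
    covariates = z,
    lambda = c(1e9, 1e8), cv_folds = 3, seed = 2
  )
  expect_true(all(fit$beta == 0) || all(abs(fit$beta) < 1e-10))
  g <- glm(y ~ age + sex, family = binomial(), data = dplyr::mutate(z, y = y))
  expect_equal(fit$intercept, unname(coef(g)[1]), tolerance = 1e-4)
  expect_equal(unname(fit$alpha), unname(coef(g)[-1]), tolerance = 1e-4)
})

test_that("all-zero features with no covariates give the closed-form intercept", {
  y <- rep(c(0, 1), c(20, 60))
  feats <- matrix(0, 80, 5, dimnames = list(NULL, paste0("p", 1:5)))
  fit <- fit_penalized_logistic(feats, y, cv_folds = 3, seed = 3)
  expect_equal(fit$intercept, log(60 / 20), tolerance = 1e-8)
  expect_true(all(fit$beta == 0))
  expect_equal(unname(predict(fit, feats))[1], 0.75, tolerance = 1e-8)
})

test_that("a single strong feature is selected while noise features are not", {
  hits <- vapply(1:10, function(s) {
    set.seed(s)
    n <- 200
    y <- rep(0:1, each = n / 2)
    strong <- y * 2 + rnorm(n, sd = 0.4)
    noise <- matrix(rnorm(n * 50), n)
    feats <- cbind(strong = strong, noise)
    colnames(feats) <- c("strong", paste0("n", 1:50))
    fit <- fit_penalized_logistic(feats, y,
      lambda = c(1, 0.1), # moderate fixed penalty
      cv_folds = 5, seed = s
    )
    cf <- as.numeric(coef(fit$glmnet_fit, s = 0.1))[-1]
    cf[1] != 0 && sum(cf[-1] != 0) == 0
  }, logical(1))
  expect_gte(mean(hits), 0.95)
})

test_that("degenerate CV folds are caught", {
  y <- rep(c(0, 1), c(3, 57))
  feats <- matrix(rnorm(60 * 4), 60, dimnames = list(NULL, paste0("p", 1:4)))
  expect_error(
    fit_penalized_logistic(feats, y, cv_folds = 5, seed = 1),
    "single class"
  )
})

test_that("H = 1 gives binary weights and swap_roles requires even H", {
  sim <- tiny_dataset(15, 4, seed = 10)
  fit <- jdinac(sim$expression, sim$phenotype,
    n_splits = 1, swap_roles = FALSE, seed = 4
  )
  expect_true(all(fit$weights$weight %in% 0:1))
  expect_error(
    jdinac(sim$expression, sim$phenotype, n_splits = 3, swap_roles = TRUE),
    "even"
  )
})

test_that("weights are bounded by H and splits partition the training set", {
  sim <- tiny_dataset(12, 3, seed = 11)
  fit <- jdinac(sim$expression, sim$phenotype, n_splits = 6, seed = 5)
  expect_true(all(fit$weights$weight >= 0 & fit$weights$weight <= 6))
  for (r in fit$records) {
    expect_length(intersect(r$density_ids, r$model_ids), 0L)
    expect_setequal(c(r$density_ids, r$model_ids), sim$expression$sample_id)
  }
})

test_that("fitting is deterministic given config and seed", {
  sim <- tiny_dataset(12, 3, seed = 12)
  f1 <- jdinac(sim$expression, sim$phenotype, n_splits = 4, seed = 6)
  f2 <- jdinac(sim$expression, sim$phenotype, n_splits = 4, seed = 6)
  expect_equal(f1$weights, f2$weights)
  p1 <- predict(f1, sim$expression)
  p2 <- predict(f2, sim$expression)
  expect_equal(p1, p2)
})

test_that("prediction averages split probabilities and stays in [0, 1]", {
  sim <- tiny_dataset(12, 3, seed = 13)
  fit <- jdinac(sim$expression, sim$phenotype, n_splits = 2, seed = 7)
  # collapse to one duplicated record: average must equal the single split
  single <- fit
  single$records <- fit$records[1]
  dup <- fit
  dup$records <- fit$records[c(1, 1, 1)]
  ps <- predict(single, sim$expression)
  pd <- predict(dup, sim$expression)
  expect_equal(ps$probability, pd$probability)
  expect_true(all(ps$probability >= 0 & ps$probability <= 1))
})

test_that("prediction rejects mismatched gene sets", {
  sim <- tiny_dataset(12, 3, seed = 14)
  fit <- jdinac(sim$expression, sim$phenotype, n_splits = 2, seed = 8)
  bad <- dplyr::rename(sim$expression, XX = G001)
  expect_error(predict(fit, bad), "missing: G001")
})

test_that("truth pairs out-weigh null pairs across seeds", {
  for (s in 1:3) {
    sim <- simulate_dataset(
      n_class0 = 150, n_class1 = 150, n_genes = 10,
      planted_pairs = planted_pairs(c(1, 3), c(2, 4), rho0 = 0, rho1 = 0.8),
      seed = s
    )
    fit <- jdinac(sim$expression, sim$phenotype, n_splits = 6, seed = s)
    keys <- paste(fit$weights$gene_a, fit$weights$gene_b, sep = "|")
    truth <- paste(sim$truth$gene_a, sim$truth$gene_b, sep = "|")
    w_truth <- fit$weights$weight[keys %in% truth]
    w_null <- fit$weights$weight[!keys %in% truth]
    expect_gt(mean(w_truth), mean(w_null))
  }
})

test_that("covariate adjustment keeps recovery under confounding", {
  # class is confounded with age, but only the planted pair carries
  # expression signal; adjusted fit must still rank it on top
  confounded <- list(
    age = list(type = "continuous", mean = c(82, 87), sd = c(5, 5)),
    sex = list(type = "binary", prob = c(0.5, 0.5)),
    educ = list(type = "continuous", mean = c(16, 16), sd = c(3, 3))
  )
  neutral <- confounded
  neutral$age$mean <- c(85, 85)
  truth_rank <- function(confounders, seed) {
    sim <- simulate_dataset(
      n_class0 = 200, n_class1 = 200, n_genes = 8,
      planted_pairs = planted_pairs(c(1, 3), c(2, 4), rho0 = 0, rho1 = 0.8),
      confounders = confounders, seed = seed
    )
    fit <- jdinac(sim$expression, sim$phenotype,
      covariate_cols = c("age", "sex", "educ"), n_splits = 10, seed = 20
    )
    ranked <- tidy(fit)
    keys <- paste(ranked$gene_a, ranked$gene_b, sep = "|")
    truth <- paste(sim$truth$gene_a, sim$truth$gene_b, sep = "|")
    mean(keys[1:2] %in% truth) # precision at the number of truth pairs
  }
  prec_conf <- truth_rank(confounded, 19)
  prec_neutral <- truth_rank(neutral, 19)
  expect_gte(prec_conf, prec_neutral - 0.1)
  expect_gte(prec_conf, 0.5)
})

test_that("tidy and glance expose weights and model shape", {
  sim <- tiny_dataset(12, 3, seed = 15)
  fit <- jdinac(sim$expression, sim$phenotype, n_splits = 2, seed = 9)
  td <- tidy(fit)
  expect_named(td, c("gene_a", "gene_b", "weight", "mean_abs_coef"))
  expect_true(all(diff(td$weight) <= 0))
  gl <- glance(fit)
  expect_equal(gl$n_pairs, 3L)
  expect_equal(gl$n_splits, 2L)
})
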