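test_that("planted correlations are recovered within Fisher-z tolerance", {
  sim <- simulate_dataset(
    n_class0 = 500, n_class1 = 500, n_genes = 4,
    planted_pairs = planted_pairs(1, 2, rho0 = 0, rho1 = 0.8), seed = 11
  )
  y <- sim$phenotype$label
  m <- as.matrix(sim$expression[-1])
  # Fisher-z SE at n = 500 is ~0.045; +-0.08 is just under 2 SE
  expect_lt(abs(cor(m[y == 1, 1], m[y == 1, 2]) - 0.8), 0.08)
  expect_lt(abs(cor(m[y == 0, 1], m[y == 0, 2]) - 0.0), 0.08)
  expect_equal(sim$truth, tibble::tibble(gene_a = "G001", gene_b = "G002"))
})

test_that("identical rho in both classes means no signal and empty truth", {
  sim <- simulate_dataset(
    n_class0 = 40, n_class1 = 40, n_genes = 4,
    planted_pairs = planted_pairs(1, 2, rho0 = 0.5, rho1 = 0.5), seed = 3
  )
  expect_equal(nrow(sim$truth), 0L)
})

test_that("generation is deterministic under seed and varies across seeds", {
  a <- simulate_dataset(n_class0 = 10, n_class1 = 10, n_genes = 3, seed = 9)
  b <- simulate_dataset(n_class0 = 10, n_class1 = 10, n_genes = 3, seed = 9)
  c <- simulate_dataset(n_class0 = 10, n_class1 = 10, n_genes = 3, seed = 10)
  expect_identical(a, b)
  expect_false(identical(a$expression, c$expression))
})

test_that("zero inflation hits the configured per-gene fraction", {
  q <- 0.4
  sim <- simulate_dataset(
    n_class0 = 500, n_class1 = 500, n_genes = 3,
    zero_inflation = c(q, 0, 0), seed = 13
  )
  frac <- colMeans(as.matrix(sim$expression[-1]) == 0)
  expect_lt(abs(frac[["G001"]] - q), 3 * sqrt(q * (1 - q) / 1000))
  expect_equal(unname(frac[["G002"]]), 0)
})

test_that("pair validation rejects shared genes and out-of-range rho", {
  expect_error(
    simulate_dataset(
      n_class0 = 5, n_class1 = 5, n_genes = 4,
      planted_pairs = planted_pairs(c(1, 1), c(2, 3), rho1 = 0.5)
    ),
    "share genes"
  )
  sim <- simulate_dataset(
    n_class0 = 20, n_class1 = 20, n_genes = 4,
    planted_pairs = planted_pairs(c(1, 1), c(2, 3), rho1 = 0.5),
    allow_shared_genes = TRUE, seed = 2
  )
  expect_equal(nrow(sim$truth), 2L)
  expect_error(
    simulate_dataset(
      n_class0 = 5, n_class1 = 5, n_genes = 4,
      planted_pairs = planted_pairs(1, 2, rho1 = 1.2)
    )
  )
})

test_that("nonlinear planted pair creates dependence with near-zero correlation", {
  sim <- simulate_dataset(
    n_class0 = 400, n_class1 = 400, n_genes = 4,
    planted_pairs = planted_pairs(1, 2, nonlinear = TRUE), seed = 17
  )
  y <- sim$phenotype$label
  m <- as.matrix(sim$expression[-1])
  expect_lt(abs(cor(m[y == 1, 1], m[y == 1, 2])), 0.15)
  # dependence is quadratic: correlate partner with the squared driver
  expect_gt(cor(m[y == 1, 1]^2, m[y == 1, 2]), 0.7)
  expect_equal(nrow(sim$truth), 1L)
})

test_that("demographics emulator moments converge to the configured values", {
  conf <- list(
    age = list(type = "continuous", mean = c(84.60, 88.29), sd = c(5.32, 3.08)),
    sex = list(type = "binary", prob = c(0.599, 0.689))
  )
  ph <- simulate_demographics(10000, 10000, confounders = conf, seed = 21)
  a1 <- ph$age[ph$label == 1]
  a0 <- ph$age[ph$label == 0]
  expect_lt(abs(mean(a1) - 88.29), 3 * 3.08 / sqrt(10000))
  expect_lt(abs(mean(a0) - 84.60), 3 * 5.32 / sqrt(10000))
  p1 <- mean(ph$sex[ph$label == 1])
  expect_lt(abs(p1 - 0.689), 3 * sqrt(0.689 * 0.311 / 10000))
})

test_that("demographics emulator edge cases: empty class, zero sd, bad proportion", {
  conf <- list(age = list(type = "continuous", mean = c(80, 85), sd = c(0, 0)))
  ph <- simulate_demographics(0, 4, confounders = conf, seed = 1)
  expect_equal(nrow(ph), 4L)
  expect_equal(unique(ph$label), 1L)
  expect_equal(ph$age, rep(85, 4))
  expect_error(
    simulate_demographics(2, 2,
      confounders = list(sex = list(type = "binary", prob = c(1.2, 0.5)))
    ),
    "proportions"
  )
})
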