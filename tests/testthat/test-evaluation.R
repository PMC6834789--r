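test_that("auc handles separation, ties, and the worked example", {
  expect_equal(auc(c(1, 2, 3, 4), c(0, 0, 1, 1)), 1)
  expect_equal(auc(rep(0.5, 10), rep(0:1, 5)), 0.5)
  expect_equal(auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)), 0.75)
  expect_equal(
    auc(c(0.2, 0.8), c(0, 1)) + auc(c(0.2, 0.8), c(1, 0)), 1
  )
  expect_error(auc(1:3, c(1, 1, 1)), "both classes")
})

test_that("rank-form auc equals trapezoidal ROC area on tied random vectors", {
  set.seed(60)
  for (i in 1:100) {
    n <- sample(10:40, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE) # heavy ties
    labels <- rbinom(n, 1, 0.5)
    if (length(unique(labels)) < 2) labels[1:2] <- c(0, 1)
    expect_equal(auc(scores, labels), trapezoid_auc(scores, labels), tolerance = 1e-12)
  }
})

test_that("roc_points is also consistent with the rank AUC", {
  set.seed(61)
  scores <- round(runif(50), 1)
  labels <- rbinom(50, 1, 0.4)
  rp <- roc_points(scores, labels)
  trap <- sum(diff(rp$fpr) * (head(rp$tpr, -1) + rp$tpr[-1]) / 2)
  expect_equal(trap, auc(scores, labels))
  expect_equal(rp$fpr[1], 0)
  expect_equal(rp$tpr[nrow(rp)], 1)
})

test_that("classification metrics reproduce a known confusion table", {
  # 110 test samples: TP=45, FN=13, TN=42, FP=10
  scores <- c(rep(0.9, 45), rep(0.1, 13), rep(0.1, 42), rep(0.9, 10))
  labels <- c(rep(1, 58), rep(0, 52))
  m <- classification_metrics(scores, labels)
  expect_equal(m$sensitivity, 45 / 58)
  expect_equal(m$specificity, 42 / 52)
  expect_equal(m$accuracy, 87 / 110)
  expect_equal(m$precision, 45 / 55)
})

test_that("metric edge cases: all positive, threshold above max", {
  labels <- rep(0:1, 5)
  all_pos <- classification_metrics(rep(1, 10), labels, threshold = 0.5)
  expect_equal(all_pos$sensitivity, 1)
  expect_equal(all_pos$specificity, 0)
  high <- suppressWarnings(
    classification_metrics(runif(10, 0, 0.4), labels, threshold = 0.9)
  )
  expect_equal(high$sensitivity, 0)
  expect_true(is.na(high$precision))
  expect_warning(
    classification_metrics(runif(10, 0, 0.4), labels, threshold = 0.9),
    "precision"
  )
})

test_that("bootstrap CI is deterministic, degenerate on perfect separation,", {
  scores <- c(runif(20, 0.6, 1), runif(20, 0, 0.4))
  labels <- rep(c(1, 0), each = 20)
  ci <- bootstrap_ci(auc, scores, labels, n_boot = 200, seed = 62)
  expect_identical(ci, bootstrap_ci(auc, scores, labels, n_boot = 200, seed = 62))
  expect_equal(unname(ci), c(1, 1))
})

test_that("bootstrap CI width shrinks roughly as 1/sqrt(n)", {
  widths <- vapply(c(50, 200, 800), function(n) {
    set.seed(63)
    labels <- rep(0:1, n / 2)
    scores <- labels * 0.8 + rnorm(n, sd = 0.8)
    ci <- bootstrap_ci(auc, scores, labels, n_boot = 400, seed = 64)
    ci[["high"]] - ci[["low"]]
  }, numeric(1))
  expect_true(all(diff(widths) < 0))
  # 16-fold n increase should shrink width ~4x; allow generous slack
  expect_gt(widths[1] / widths[3], 2.5)
})

test_that("delong test: identical scores give p = 1 exactly", {
  set.seed(65)
  s <- runif(40)
  y <- rep(0:1, 20)
  res <- delong_test(s, s, y)
  expect_equal(res$p_value, 1)
  expect_equal(res$auc_a, res$auc_b)
})

test_that("delong test flags strongly opposed classifiers", {
  set.seed(90)
  y <- rep(0:1, each = 30)
  good <- y + rnorm(60, sd = 0.5)
  anti <- -y + rnorm(60, sd = 0.5)
  res <- delong_test(good, anti, y)
  expect_gt(abs(res$z), 3.29)
  expect_lt(res$p_value, 0.001)
})

test_that("delong errors on degenerate variance with unequal AUCs", {
  y <- rep(0:1, each = 5)
  expect_error(delong_test(as.numeric(y), 1 - y, y), "zero variance")
})

test_that("delong agrees with pROC on random correlated scores", {
  skip_if_not_installed("pROC")
  set.seed(66)
  y <- rbinom(80, 1, 0.5)
  y[1:2] <- 0:1
  base <- rnorm(80)
  a <- base + y + rnorm(80)
  b <- 0.5 * base + 0.8 * y + rnorm(80)
  got <- delong_test(a, b, y)
  ref <- pROC::roc.test(
    pROC::roc(y, a, quiet = TRUE), pROC::roc(y, b, quiet = TRUE),
    method = "delong"
  )
  expect_equal(got$p_value, unname(ref$p.value), tolerance = 1e-10)
  expect_equal(got$auc_a, as.numeric(ref$roc1$auc), tolerance = 1e-10)
})

test_that("delong variance tracks the stratified-bootstrap variance of dAUC", {
  set.seed(67)
  n <- 200
  y <- rep(0:1, each = n / 2)
  base <- rnorm(n)
  a <- base + 1.2 * y + rnorm(n, sd = 0.8)
  b <- 0.6 * base + 0.9 * y + rnorm(n, sd = 0.9)
  res <- delong_test(a, b, y)
  var_delong <- ((res$auc_a - res$auc_b) / res$z)^2
  i1 <- which(y == 1)
  i0 <- which(y == 0)
  d <- replicate(2000, {
    idx <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
    auc(a[idx], y[idx]) - auc(b[idx], y[idx])
  })
  expect_lt(abs(var_delong - var(d)) / var(d), 0.2)
})

test_that("cohort table reproduces printed demographic statistics", {
  pheno <- tibble::tibble(
    sample_id = as.character(1:365),
    label = rep(c(1L, 0L), c(193, 172)),
    female = c(rep(1, 133), rep(0, 60), rep(1, 103), rep(0, 69)),
    apoe4 = c(rep(1, 69), rep(0, 124), rep(1, 28), rep(0, 144))
  )
  tab <- cohort_table(pheno)
  sex <- tab[tab$variable == "female", ]
  expect_equal(sex$class1, "133 (68.9)")
  expect_equal(sex$class0, "103 (59.9)")
  expect_equal(sex$p, "0.072")
  apoe <- tab[tab$variable == "apoe4", ]
  expect_equal(apoe$p, "<0.001")
  # chi-square statistic itself, via the direct formula
  stat <- chisq.test(
    rbind(c(69, 124), c(28, 144)),
    correct = FALSE
  )$statistic
  expect_equal(unname(round(stat, 1)), 17.7)
})

test_that("cohort table handles identical groups and constant covariates", {
  pheno <- tibble::tibble(
    sample_id = as.character(1:40),
    label = rep(0:1, each = 20),
    bin = rep(c(0, 1), 20),
    flat = 1
  )
  tab <- cohort_table(pheno)
  expect_equal(tab$p[tab$variable == "bin"], "1.000")
  expect_true(is.na(tab$p_value[tab$variable == "flat"]))
  cont <- tibble::tibble(
    sample_id = as.character(1:60), label = rep(0:1, 30),
    age = rnorm(60, 80)
  )
  tab2 <- cohort_table(cont, var_equal = TRUE)
  expect_match(tab2$class1, "^[0-9.]+ \\([0-9.]+\\)$")
})

test_that("evaluate_predictions assembles a full report", {
  set.seed(68)
  n <- 60
  pheno <- tibble::tibble(
    sample_id = sprintf("s%02d", 1:n), label = rep(0:1, n / 2)
  )
  mk <- function(shift) tibble::tibble(
    sample_id = pheno$sample_id,
    probability = plogis(shift * pheno$label + rnorm(n))
  )
  rep <- evaluate_predictions(
    list(good = mk(2), weak = mk(0.3)), pheno,
    n_boot = 100, seed = 69
  )
  td <- tidy(rep)
  expect_setequal(
    unique(td$metric),
    c("auc", "accuracy", "sensitivity", "specificity", "precision")
  )
  expect_true(all(td$ci_low <= td$ci_high))
  expect_true(all(td$estimate >= 0 & td$estimate <= 1, na.rm = TRUE))
  expect_equal(nrow(rep$delong), 1L)
  expect_gt(
    td$estimate[td$method == "good" & td$metric == "auc"],
    td$estimate[td$method == "weak" & td$metric == "auc"]
  )
  expect_s3_class(autoplot(rep), "ggplot")
})
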