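# Evaluation suite: Mann-Whitney AUC, threshold metrics, stratified
# percentile-bootstrap confidence intervals, the DeLong test for correlated
# AUCs, ROC export, and the cohort demographics table.

#' Area under the ROC curve (Mann-Whitney form)
#'
#' The mean over all (case, control) score pairs of 1 if the case scores
#' higher, 0.5 on a tie, 0 otherwise — identical to the trapezoidal area
#' under the tie-aware ROC curve.
#'
#' @param scores Numeric prediction scores.
#' @param labels 0/1 labels, both classes present.
#' @return AUC in `[0, 1]`.
#' @examples
#' auc(c(0.1, 0.4, 0.35, 0.8), c(0, 0, 1, 1)) # 0.75
#' @export
auc <- function(scores, labels) {
  check_binary_label(labels)
  stopifnot(length(scores) == length(labels))
  r <- rank(scores)
  n1 <- sum(labels == 1)
  n0 <- sum(labels == 0)
  (sum(r[labels == 1]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' ROC curve points
#'
#' Tie-aware ROC: one point per distinct score threshold, from (0, 0) to
#' (1, 1), with FPR/TPR computed by predicting positive at or above the
#' threshold.
#'
#' @inheritParams auc
#' @return Tibble with `threshold`, `fpr`, `tpr` (descending threshold).
#' @export
roc_points <- function(scores, labels) {
  check_binary_label(labels)
  ord <- order(scores, decreasing = TRUE)
  s <- scores[ord]
  y <- labels[ord]
  keep <- !duplicated(s, fromLast = TRUE) # last index of each tie block
  tibble::tibble(
    threshold = c(Inf, s[keep]),
    fpr = c(0, cumsum(y == 0)[keep] / sum(y == 0)),
    tpr = c(0, cumsum(y == 1)[keep] / sum(y == 1))
  )
}

#' Threshold classification metrics
#'
#' Predicted class is 1 iff `score >= threshold`. Precision is `NA` (with a
#' warning) when nothing is predicted positive.
#'
#' @inheritParams auc
#' @param threshold Probability cutoff; default 0.5.
#' @return One-row tibble: `accuracy`, `sensitivity`, `specificity`,
#'   `precision`.
#' @export
classification_metrics <- function(scores, labels, threshold = 0.5) {
  check_binary_label(labels)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1)
  fp <- sum(pred == 1 & labels == 0)
  tn <- sum(pred == 0 & labels == 0)
  fn <- sum(pred == 0 & labels == 1)
  precision <- if (tp + fp == 0) {
    warn("no sample predicted positive; precision undefined")
    NA_real_
  } else {
    tp / (tp + fp)
  }
  tibble::tibble(
    accuracy = (tp + tn) / length(labels),
    sensitivity = tp / (tp + fn),
    specificity = tn / (tn + fp),
    precision = precision
  )
}

#' Stratified percentile bootstrap confidence interval
#'
#' Resamples within each class (preserving both class counts), recomputes
#' `metric_fn(scores, labels)` on each resample and returns the percentile
#' interval. With a degenerate (constant) metric the interval collapses to
#' a point.
#'
#' @param metric_fn Function `(scores, labels) -> scalar` (e.g. [auc()], or
#'   a wrapper around one column of [classification_metrics()]).
#' @inheritParams auc
#' @param n_boot Number of bootstrap resamples; default 2000.
#' @param alpha Two-sided miscoverage; default 0.05 for a 95% interval.
#' @param seed Integer seed; identical seeds give identical intervals.
#' @return Named numeric vector `c(low, high)`.
#' @export
bootstrap_ci <- function(metric_fn, scores, labels, n_boot = 2000,
                         alpha = 0.05, seed = NULL) {
  check_binary_label(labels)
  stopifnot(length(scores) >= 10)
  i1 <- which(labels == 1)
  i0 <- which(labels == 0)
  run <- function() {
    vapply(seq_len(n_boot), function(b) {
      idx <- c(sample(i1, replace = TRUE), sample(i0, replace = TRUE))
      metric_fn(scores[idx], labels[idx])
    }, numeric(1))
  }
  stats <- if (is.null(seed)) run() else withr::with_seed(seed, run())
  q <- stats::quantile(stats, c(alpha / 2, 1 - alpha / 2), na.rm = TRUE, names = FALSE)
  c(low = q[1], high = q[2])
}

# DeLong structural components: V10[i] is the placement of case i among
# controls, V01[j] the placement of control j among cases.
delong_components <- function(scores, labels) {
  cases <- scores[labels == 1]
  controls <- scores[labels == 0]
  psi <- outer(cases, controls, function(a, b) (a > b) + 0.5 * (a == b))
  list(v10 = rowMeans(psi), v01 = colMeans(psi), auc = mean(psi))
}

#' DeLong test for two correlated AUCs
#'
#' Compares the AUCs of two score vectors computed on the same samples,
#' using the structural-components estimator of the variance of the AUC
#' difference (which accounts for their correlation). `z = dAUC / SE` and
#' the p-value is two-sided standard normal.
#'
#' @param scores_a,scores_b Score vectors on the same samples.
#' @inheritParams auc
#' @return One-row tibble: `auc_a`, `auc_b`, `z`, `p_value`.
#' @export
delong_test <- function(scores_a, scores_b, labels) {
  check_binary_label(labels)
  stopifnot(length(scores_a) == length(labels), length(scores_b) == length(labels))
  ca <- delong_components(scores_a, labels)
  cb <- delong_components(scores_b, labels)
  m <- length(ca$v10)
  n <- length(ca$v01)
  s10 <- stats::cov(cbind(ca$v10, cb$v10))
  s01 <- stats::cov(cbind(ca$v01, cb$v01))
  var_diff <- (s10[1, 1] + s10[2, 2] - 2 * s10[1, 2]) / m +
    (s01[1, 1] + s01[2, 2] - 2 * s01[1, 2]) / n
  d <- ca$auc - cb$auc
  if (var_diff <= 0) {
    if (abs(d) < 1e-12) {
      return(tibble::tibble(auc_a = ca$auc, auc_b = cb$auc, z = 0, p_value = 1))
    }
    abort("zero variance estimate with unequal AUCs; DeLong test undefined")
  }
  z <- d / sqrt(var_diff)
  tibble::tibble(
    auc_a = ca$auc, auc_b = cb$auc, z = z,
    p_value = 2 * pnorm(-abs(z))
  )
}

#' Evaluate one or more prediction sets against labels
#'
#' Computes AUC, accuracy, sensitivity, specificity and precision with
#' stratified percentile-bootstrap 95% confidence intervals for each
#' method, ROC points, and DeLong comparisons between every method pair.
#'
#' @param predictions Named list of prediction tibbles (`sample_id`,
#'   `probability`), one per method, all on the same samples.
#' @param pheno Phenotype tibble supplying the 0/1 `label` per sample.
#' @param threshold Classification cutoff; default 0.5.
#' @param n_boot,alpha,seed Bootstrap controls; see [bootstrap_ci()].
#' @return An `evaluation_report`; see [tidy.evaluation_report()] and
#'   [autoplot.evaluation_report()].
#' @export
evaluate_predictions <- function(predictions, pheno, threshold = 0.5,
                                 n_boot = 2000, alpha = 0.05, seed = NULL) {
  stopifnot(is.list(predictions), length(predictions) >= 1)
  if (is.null(names(predictions)) || any(!nzchar(names(predictions)))) {
    abort("predictions must be a named list of per-method tibbles")
  }
  metric_fns <- list(
    auc = auc,
    accuracy = function(s, y) classification_metrics(s, y, threshold)$accuracy,
    sensitivity = function(s, y) classification_metrics(s, y, threshold)$sensitivity,
    specificity = function(s, y) classification_metrics(s, y, threshold)$specificity,
    precision = function(s, y) {
      suppressWarnings(classification_metrics(s, y, threshold)$precision)
    }
  )
  per_method <- purrr::imap(predictions, function(preds, method) {
    ph <- pheno[match(preds$sample_id, pheno$sample_id), , drop = FALSE]
    if (anyNA(ph$label)) abort("prediction samples missing from phenotype")
    s <- preds$probability
    y <- ph$label
    metrics <- purrr::imap_dfr(metric_fns, function(fn, nm) {
      ci <- bootstrap_ci(fn, s, y,
        n_boot = n_boot, alpha = alpha,
        seed = if (is.null(seed)) NULL else stage_seed(seed, paste0(method, nm))
      )
      tibble::tibble(
        method = method, metric = nm, estimate = fn(s, y),
        ci_low = ci[["low"]], ci_high = ci[["high"]]
      )
    })
    list(metrics = metrics, roc = roc_points(s, y), scores = s, labels = y)
  })
  combos <- if (length(predictions) >= 2) utils::combn(names(predictions), 2) else NULL
  delong <- if (is.null(combos)) {
    tibble::tibble(
      method_a = character(), method_b = character(),
      auc_a = double(), auc_b = double(), z = double(), p_value = double()
    )
  } else {
    purrr::map_dfr(seq_len(ncol(combos)), function(k) {
      a <- combos[1, k]
      b <- combos[2, k]
      dplyr::bind_cols(
        tibble::tibble(method_a = a, method_b = b),
        delong_test(
          per_method[[a]]$scores, per_method[[b]]$scores,
          per_method[[a]]$labels
        )
      )
    })
  }
  structure(
    list(
      metrics = purrr::map_dfr(per_method, "metrics"),
      roc = purrr::imap_dfr(per_method, function(x, nm) {
        dplyr::mutate(x$roc, method = nm, .before = 1)
      }),
      delong = delong,
      settings = list(
        threshold = threshold, n_boot = n_boot, alpha = alpha, seed = seed
      )
    ),
    class = "evaluation_report"
  )
}

#' Tidy an evaluation report
#'
#' @param x An `evaluation_report`.
#' @param ... Unused.
#' @return Tibble `method`, `metric`, `estimate`, `ci_low`, `ci_high`.
#' @method tidy evaluation_report
#' @export
tidy.evaluation_report <- function(x, ...) x$metrics

#' @export
print.evaluation_report <- function(x, ...) {
  cat("evaluation report\n")
  print(
    tidyr::pivot_wider(x$metrics,
      id_cols = "metric", names_from = "method",
      values_from = "estimate"
    )
  )
  if (nrow(x$delong) > 0) {
    cat("DeLong AUC comparisons:\n")
    print(x$delong)
  }
  invisible(x)
}

#' ROC curves for an evaluation report
#'
#' @param object An `evaluation_report`.
#' @param ... Unused.
#' @return A ggplot object with one ROC curve per method.
#' @export
autoplot.evaluation_report <- function(object, ...) {
  ggplot2::ggplot(
    object$roc,
    ggplot2::aes(.data$fpr, .data$tpr, colour = .data$method)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey") +
    ggplot2::geom_step(linewidth = 0.8) +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "False positive rate (1 - specificity)",
      y = "True positive rate (sensitivity)"
    ) +
    ggplot2::theme_minimal()
}

#' Cohort demographics table with group-comparison statistics
#'
#' Summarizes each covariate by diagnostic group. Binary covariates are
#' reported as count (percent to 1 decimal) per group and compared with a
#' two-sided Pearson chi-square test (1 df, no continuity correction);
#' continuous covariates as mean (SD to 2 decimals) compared with a
#' two-sided two-sample t-test. P-values print to 3 decimals, "<0.001"
#' below that. A covariate constant in both groups is reported without a
#' statistic.
#'
#' @param pheno Phenotype tibble (`sample_id`, 0/1 `label`, covariates).
#' @param covariates Covariate columns to summarize; default all non-id,
#'   non-label columns. Columns whose values are all in \{0, 1\} are
#'   treated as binary.
#' @param var_equal Use the pooled-variance t-test instead of Welch.
#' @return Tibble: `variable`, `class1` and `class0` formatted summaries,
#'   numeric `p_value`, formatted `p`.
#' @examples
#' pheno <- tibble::tibble(
#'   sample_id = as.character(1:365),
#'   label = rep(c(1L, 0L), c(193, 172)),
#'   female = c(rep(1, 133), rep(0, 60), rep(1, 103), rep(0, 69))
#' )
#' cohort_table(pheno) # chi-square p = 0.072
#' @export
cohort_table <- function(pheno, covariates = NULL, var_equal = FALSE) {
  check_binary_label(pheno$label)
  covariates <- covariates %||% setdiff(names(pheno), c("sample_id", "label"))
  g1 <- pheno$label == 1
  rows <- purrr::map_dfr(covariates, function(cv) {
    x <- pheno[[cv]]
    x1 <- x[g1]
    x0 <- x[!g1]
    binary <- all(x %in% c(0, 1))
    if (var(x1) == 0 && var(x0) == 0) {
      return(tibble::tibble(
        variable = cv,
        class1 = format_summary(x1, binary), class0 = format_summary(x0, binary),
        p_value = NA_real_, p = "constant in both groups"
      ))
    }
    p <- if (binary) {
      tab <- rbind(
        c(sum(x1 == 1), sum(x1 == 0)),
        c(sum(x0 == 1), sum(x0 == 0))
      )
      chisq.test(tab, correct = FALSE)$p.value
    } else {
      t.test(x1, x0, var.equal = var_equal)$p.value
    }
    tibble::tibble(
      variable = cv,
      class1 = format_summary(x1, binary), class0 = format_summary(x0, binary),
      p_value = p, p = format_pvalue(p)
    )
  })
  rows
}

format_summary <- function(x, binary) {
  if (binary) {
    sprintf("%d (%.1f)", sum(x == 1), 100 * mean(x == 1))
  } else {
    sprintf("%.2f (%.2f)", mean(x), sd(x))
  }
}

format_pvalue <- function(p) {
  if (is.na(p)) return(NA_character_)
  if (p < 0.001) "<0.001" else sprintf("%.3f", p)
}
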