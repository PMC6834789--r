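# Single-gene prediction baselines: random forest and L1-penalized
# logistic regression on the gene columns themselves. Covariates are
# excluded by default so the baselines see exactly the individual genes.

#' Fit a single-gene baseline classifier
#'
#' `"rf"` fits a standard classification random forest on the gene columns;
#' `"plr"` fits the same penalized-logistic machinery used by [jdinac()]
#' but with individual genes (not pair features) as the penalized
#' predictors. Covariates may be added as predictors (unpenalized for PLR)
#' via `covariate_cols`; the default is genes only.
#'
#' @param expr Training expression tibble.
#' @param pheno Training phenotype tibble (`sample_id`, `label`, covariates).
#' @param method `"rf"` or `"plr"`.
#' @param covariate_cols Optional covariate columns to include.
#' @param n_trees Random-forest ensemble size; default 500.
#' @param cv_folds,lambda PLR controls; see [fit_penalized_logistic()].
#' @param seed Integer seed.
#' @return A `baseline_model`.
#' @export
fit_baseline <- function(expr, pheno, method = c("rf", "plr"),
                         covariate_cols = NULL, n_trees = 500,
                         cv_folds = 5, lambda = NULL, seed = NULL) {
  method <- match.arg(method)
  pheno <- align_phenotype(expr, pheno)
  y <- pheno$label
  check_binary_label(y)
  x <- expr_to_matrix(expr)
  covariates <- if (length(covariate_cols)) pheno[covariate_cols] else NULL
  fit <- if (method == "rf") {
    xx <- if (is.null(covariates)) x else cbind(x, as.matrix(covariates))
    run <- function() {
      randomForest::randomForest(xx, factor(y, levels = c(0, 1)), ntree = n_trees)
    }
    if (is.null(seed)) run() else withr::with_seed(seed, run())
  } else {
    fit_penalized_logistic(
      x, y,
      covariates = covariates, lambda = lambda,
      cv_folds = cv_folds, seed = seed
    )
  }
  structure(
    list(
      method = method, fit = fit, genes = colnames(x),
      covariate_cols = covariate_cols,
      config = list(n_trees = n_trees, cv_folds = cv_folds, seed = seed)
    ),
    class = "baseline_model"
  )
}

#' Predict class probabilities from a baseline classifier
#'
#' @param object A `baseline_model`.
#' @param expr New expression tibble (same genes as training).
#' @param pheno New phenotype tibble; required only if the baseline was fit
#'   with covariates.
#' @param ... Unused.
#' @return Tibble with `sample_id` and `probability`.
#' @export
predict.baseline_model <- function(object, expr, pheno = NULL, ...) {
  if (!setequal(gene_ids(expr), object$genes)) {
    abort("gene columns do not match the baseline's training genes")
  }
  x <- expr_to_matrix(expr[c("sample_id", object$genes)])
  covariates <- NULL
  if (length(object$covariate_cols)) {
    if (is.null(pheno)) abort("pheno is required: the baseline uses covariates")
    pheno <- align_phenotype(expr, pheno)
    covariates <- pheno[object$covariate_cols]
  }
  p <- if (object$method == "rf") {
    xx <- if (is.null(covariates)) x else cbind(x, as.matrix(covariates))
    unname(predict(object$fit, xx, type = "prob")[, "1"])
  } else {
    predict(object$fit, x, covariates = covariates)
  }
  tibble::tibble(sample_id = expr$sample_id, probability = p)
}

#' @export
print.baseline_model <- function(x, ...) {
  cat(sprintf(
    "baseline %s model on %d genes%s\n",
    toupper(x$method), length(x$genes),
    if (length(x$covariate_cols)) {
      paste0(" + covariates (", paste(x$covariate_cols, collapse = ", "), ")")
    } else ""
  ))
  invisible(x)
}
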