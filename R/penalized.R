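# L1-penalized logistic regression with unpenalized confounders, the
# per-split workhorse of the pairwise classifier and of the single-gene
# PLR baseline. glmnet does the optimization; the penalty falls only on
# the feature block (penalty.factor = 1), never on covariates or the
# intercept (penalty.factor = 0).

#' Fit an L1-penalized logistic regression with unpenalized covariates
#'
#' Maximizes the binomial log-likelihood minus `lambda * sum(|beta|)` over
#' the feature coefficients, with covariates and intercept exempt from the
#' penalty. `lambda` is chosen by stratified k-fold cross-validation
#' minimizing mean binomial deviance. In the `lambda -> Inf` limit every
#' feature coefficient is zero and the fit coincides with the unpenalized
#' covariate-only logistic model.
#'
#' @param features Numeric matrix or tibble of penalized predictors (a
#'   `sample_id` column, if present, is dropped).
#' @param y 0/1 response vector, both classes present.
#' @param covariates Optional numeric matrix/tibble of unpenalized
#'   confounders (same row order).
#' @param lambda Optional decreasing lambda sequence; default glmnet path.
#' @param cv_folds Number of CV folds (stratified by class).
#' @param seed Integer seed controlling fold assignment.
#' @return A `penalized_logistic_fit` with elements `intercept`,
#'   `alpha` (covariate coefficients), `beta` (named feature coefficients),
#'   `lambda` (selected value) and `cv` metadata.
#' @export
fit_penalized_logistic <- function(features, y, covariates = NULL,
                                   lambda = NULL, cv_folds = 5, seed = NULL) {
  check_binary_label(y)
  fm <- as_predictor_matrix(features)
  zm <- if (is.null(covariates)) NULL else as_predictor_matrix(covariates)
  stopifnot(nrow(fm) == length(y), is.null(zm) || nrow(zm) == length(y))
  if (is.null(colnames(fm))) colnames(fm) <- paste0("f", seq_len(ncol(fm)))
  feat_names <- colnames(fm)
  cov_names <- if (is.null(zm)) character() else colnames(zm)

  varying <- apply(fm, 2, function(col) max(col) > min(col))
  x <- cbind(zm, fm[, varying, drop = FALSE])
  pf <- c(rep(0, length(cov_names)), rep(1, sum(varying)))

  if (sum(varying) == 0) {
    # No informative penalized column: the model collapses to the exact
    # covariate-only (or intercept-only) unpenalized logistic fit.
    return(covariate_only_fit(y, zm, cov_names, feat_names))
  }
  padded <- FALSE
  if (ncol(x) == 1) { # glmnet needs >= 2 columns
    x <- cbind(x, `..pad` = 0)
    pf <- c(pf, 1)
    padded <- TRUE
  }

  make_foldid <- function() {
    id <- integer(length(y))
    for (cl in c(0, 1)) {
      idx <- which(y == cl)
      id[idx] <- sample(rep_len(seq_len(cv_folds), length(idx)))
    }
    id
  }
  if (min(table(y)) < cv_folds) {
    abort("a cross-validation fold would have a single class; reduce cv_folds")
  }
  run_cv <- function(fold_seed) {
    foldid <- if (is.null(fold_seed)) make_foldid() else {
      withr::with_seed(fold_seed, make_foldid())
    }
    # glmnet warns about classes with < 8 observations in every small split
    # and CV fold; that is the expected regime here, so silence just that.
    withCallingHandlers(
      glmnet::cv.glmnet(
        x, y,
        family = "binomial", penalty.factor = pf,
        foldid = foldid, lambda = lambda, type.measure = "deviance"
      ),
      warning = function(w) {
        if (grepl("fewer than 8\\s+observations|grouped=FALSE|empty model|Convergence",
                  conditionMessage(w))) {
          invokeRestart("muffleWarning")
        }
      }
    )
  }
  # Unpenalized covariates can quasi-separate a very small CV fold, making
  # the path fit diverge; re-drawing the folds usually resolves it. The
  # last-resort fallback is the conservative covariate-only model.
  cv <- NULL
  for (attempt in 0:2) {
    fold_seed <- if (is.null(seed)) NULL else seed + attempt
    cv <- tryCatch(run_cv(fold_seed), error = function(e) NULL)
    if (!is.null(cv)) break
  }
  if (is.null(cv)) {
    warn("penalized fit did not converge on any fold draw; returning the covariate-only model")
    return(covariate_only_fit(y, zm, cov_names, feat_names))
  }
  cf <- as.numeric(coef(cv, s = "lambda.min"))
  names(cf) <- c("(Intercept)", colnames(x))
  beta <- setNames(rep(0, length(feat_names)), feat_names)
  kept <- setdiff(colnames(x), c(cov_names, "..pad"))
  beta[kept] <- cf[kept]
  fit <- list(
    intercept = unname(cf[1]),
    alpha = if (length(cov_names)) cf[cov_names] else numeric(),
    beta = beta,
    lambda = cv$lambda.min,
    cv = list(lambda = cv$lambda, cvm = cv$cvm, folds = cv_folds),
    glmnet_fit = cv,
    cov_names = cov_names, feat_names = feat_names, padded = padded
  )
  structure(fit, class = "penalized_logistic_fit")
}

covariate_only_fit <- function(y, zm, cov_names, feat_names) {
  df <- data.frame(y = y)
  form <- "y ~ 1"
  if (!is.null(zm)) {
    df <- cbind(df, as.data.frame(zm))
    form <- paste("y ~", paste(cov_names, collapse = " + "))
  }
  g <- glm(stats::as.formula(form), family = binomial(), data = df)
  fit <- list(
    intercept = unname(coef(g)[1]),
    alpha = if (length(cov_names)) coef(g)[cov_names] else numeric(),
    beta = setNames(rep(0, length(feat_names)), feat_names),
    lambda = Inf, cv = NULL, glmnet_fit = NULL,
    cov_names = cov_names, feat_names = feat_names
  )
  structure(fit, class = "penalized_logistic_fit")
}

as_predictor_matrix <- function(x) {
  if (is.data.frame(x)) {
    x <- x[setdiff(names(x), "sample_id")]
    x <- as.matrix(x)
  }
  storage.mode(x) <- "double"
  x
}

#' Predicted class-1 probabilities from a penalized logistic fit
#'
#' @param object A `penalized_logistic_fit`.
#' @param features New penalized-predictor matrix/tibble (same columns).
#' @param covariates New covariates, if the fit used any.
#' @param ... Unused.
#' @return Numeric vector of probabilities in (0, 1).
#' @export
predict.penalized_logistic_fit <- function(object, features, covariates = NULL, ...) {
  fm <- as_predictor_matrix(features)
  if (!identical(colnames(fm), object$feat_names)) {
    fm <- fm[, object$feat_names, drop = FALSE]
  }
  eta <- object$intercept + drop(fm %*% object$beta)
  if (length(object$cov_names)) {
    zm <- as_predictor_matrix(covariates)
    eta <- eta + drop(zm[, object$cov_names, drop = FALSE] %*% object$alpha)
  }
  stats::plogis(eta)
}

#' @export
print.penalized_logistic_fit <- function(x, ...) {
  cat(sprintf(
    "penalized logistic fit: %d features (%d selected), %d unpenalized covariates, lambda = %.4g\n",
    length(x$beta), sum(abs(x$beta) > 1e-8), length(x$alpha), x$lambda
  ))
  invisible(x)
}
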