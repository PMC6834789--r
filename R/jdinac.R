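# The core estimator: repeated stratified sample splitting, log-density-
# ratio feature construction, sparse logistic fits with unpenalized
# confounders, prediction averaging and selection-weight aggregation.

#' Fit the joint density-based pairwise interaction classifier
#'
#' For each of `n_splits` fits, the training samples are partitioned
#' (stratified by class, 50/50) into a density part and a model part. The
#' density part estimates class-conditional bivariate kernel densities for
#' every gene pair; the model part receives the log-density-ratio features
#' and fits an L1-penalized logistic regression in which demographic
#' covariates enter unpenalized. The per-pair selection weight `w_ij`
#' counts the splits whose fitted pair coefficient is nonzero; it ranks
#' differential pairs and defines the differential network. Predictions on
#' new samples average the per-split probabilities.
#'
#' With `swap_roles = TRUE` (default) the `n_splits` fits come from
#' `n_splits / 2` random partitions, each used in both (density, model)
#' orientations — a free variance reduction that keeps `w_ij <= n_splits`.
#'
#' @param expr Training expression tibble (`sample_id` + gene columns).
#' @param pheno Training phenotype tibble (`sample_id`, 0/1 `label`,
#'   covariate columns); aligned to `expr` by sample id.
#' @param covariate_cols Character vector of covariate columns used as
#'   unpenalized confounders; `NULL` for none.
#' @param pairs Pair universe as a tibble (`gene_a`, `gene_b`); default all
#'   unordered pairs of the genes in `expr`.
#' @param n_splits Number of per-split fits H (even when `swap_roles`).
#' @param swap_roles Reuse each random partition in both orientations.
#' @param bandwidth_scale,density_floor Density controls; see [fit_kde2()].
#' @param cv_folds,lambda Penalized-fit controls; see
#'   [fit_penalized_logistic()].
#' @param coef_tol Coefficients with `|beta| <=` this are treated as zero
#'   when counting selections (absorbs solver noise).
#' @param seed Integer seed; identical configuration and seed reproduce the
#'   model, weights and predictions exactly.
#' @return A `jdinac_fit` object; see [tidy.jdinac_fit()],
#'   [predict.jdinac_fit()], [build_network()].
#' @examples
#' \donttest{
#' sim <- simulate_dataset(
#'   n_class0 = 60, n_class1 = 60, n_genes = 6,
#'   planted_pairs = planted_pairs(1, 2, rho0 = 0, rho1 = 0.8), seed = 7
#' )
#' fit <- jdinac(sim$expression, sim$phenotype,
#'   covariate_cols = c("age", "sex"), n_splits = 4, seed = 7
#' )
#' tidy(fit)
#' }
#' @export
jdinac <- function(expr, pheno, covariate_cols = NULL, pairs = NULL,
                   n_splits = 20, swap_roles = TRUE,
                   bandwidth_scale = 1, density_floor = 1e-10,
                   cv_folds = 5, lambda = NULL, coef_tol = 1e-8,
                   seed = NULL) {
  pheno <- align_phenotype(expr, pheno)
  y <- pheno$label
  check_binary_label(y)
  if (min(sum(y == 1), sum(y == 0)) < 4) {
    abort("each class needs at least 4 training samples to split")
  }
  stopifnot(n_splits >= 1)
  if (swap_roles && n_splits %% 2 != 0) {
    abort("n_splits must be even when swap_roles = TRUE")
  }
  genes <- gene_ids(expr)
  pairs <- pairs %||% all_pairs(genes)
  pairs <- tibble::tibble(
    gene_a = pmin(pairs$gene_a, pairs$gene_b),
    gene_b = pmax(pairs$gene_a, pairs$gene_b)
  )
  keys <- pair_key(pairs$gene_a, pairs$gene_b)
  covariates <- if (length(covariate_cols)) pheno[covariate_cols] else NULL

  n_partitions <- if (swap_roles) n_splits / 2 else n_splits
  ids_by_class <- list(sort(expr$sample_id[y == 0]), sort(expr$sample_id[y == 1]))
  make_partitions <- function() {
    lapply(seq_len(n_partitions), function(b) {
      part1 <- unlist(lapply(ids_by_class, function(ids) {
        sample(ids, floor(length(ids) / 2))
      }))
      list(part1 = part1, part2 = setdiff(expr$sample_id, part1))
    })
  }
  partitions <- if (is.null(seed)) make_partitions() else {
    withr::with_seed(stage_seed(seed, "jdinac_partitions"), make_partitions())
  }

  fit_one <- function(density_ids, model_ids, fit_seed) {
    di <- expr$sample_id %in% density_ids
    mi <- expr$sample_id %in% model_ids
    feats <- logratio_features(
      expr[di, , drop = FALSE], y[di], expr[mi, , drop = FALSE],
      pairs = pairs, bandwidth_scale = bandwidth_scale,
      density_floor = density_floor
    )
    fit <- fit_penalized_logistic(
      feats, y[mi],
      covariates = if (is.null(covariates)) NULL else covariates[mi, , drop = FALSE],
      lambda = lambda, cv_folds = cv_folds, seed = fit_seed
    )
    list(density_ids = sort(density_ids), model_ids = sort(model_ids), fit = fit)
  }

  records <- list()
  for (b in seq_len(n_partitions)) {
    p <- partitions[[b]]
    s1 <- if (is.null(seed)) NULL else stage_seed(seed, paste0("cv", b, "a"))
    records[[length(records) + 1]] <- fit_one(p$part1, p$part2, s1)
    if (swap_roles) {
      s2 <- if (is.null(seed)) NULL else stage_seed(seed, paste0("cv", b, "b"))
      records[[length(records) + 1]] <- fit_one(p$part2, p$part1, s2)
    }
  }

  betas <- vapply(records, function(r) r$fit$beta[keys], numeric(length(keys)))
  betas <- matrix(betas, nrow = length(keys), dimnames = list(keys, NULL))
  selected <- abs(betas) > coef_tol
  weights <- tibble::tibble(
    gene_a = pairs$gene_a, gene_b = pairs$gene_b,
    weight = as.integer(rowSums(selected)),
    mean_abs_coef = ifelse(
      rowSums(selected) > 0,
      rowSums(abs(betas) * selected) / pmax(rowSums(selected), 1), 0
    )
  )

  structure(
    list(
      records = records,
      weights = weights,
      n_splits = n_splits,
      swap_roles = swap_roles,
      genes = genes,
      pairs = pairs,
      covariate_cols = covariate_cols,
      train_expr = expr,
      train_labels = y,
      config = list(
        n_splits = n_splits, swap_roles = swap_roles,
        bandwidth_scale = bandwidth_scale, density_floor = density_floor,
        cv_folds = cv_folds, coef_tol = coef_tol, seed = seed
      )
    ),
    class = "jdinac_fit"
  )
}

#' Predict class probabilities from a fitted pairwise classifier
#'
#' For each stored split, log-density-ratio features for the new samples
#' are computed from that split's density part and pushed through that
#' split's penalized fit; the returned probability is the arithmetic mean
#' over splits.
#'
#' @param object A `jdinac_fit`.
#' @param expr New expression tibble; gene columns must match training.
#' @param pheno New phenotype tibble carrying the covariate columns used in
#'   training (may be `NULL` if none were).
#' @param ... Unused.
#' @return Tibble with `sample_id` and `probability` in `[0, 1]`.
#' @export
predict.jdinac_fit <- function(object, expr, pheno = NULL, ...) {
  new_genes <- gene_ids(expr)
  if (!setequal(new_genes, object$genes)) {
    miss <- setdiff(object$genes, new_genes)
    extra <- setdiff(new_genes, object$genes)
    abort(paste0(
      "gene columns do not match training;",
      if (length(miss)) paste0(" missing: ", paste(head(miss, 5), collapse = ", ")) else "",
      if (length(extra)) paste0(" unexpected: ", paste(head(extra, 5), collapse = ", ")) else ""
    ))
  }
  expr <- expr[c("sample_id", object$genes)]
  covariates <- NULL
  if (length(object$covariate_cols)) {
    if (is.null(pheno)) abort("pheno with covariate columns is required for prediction")
    pheno <- align_phenotype(expr, pheno)
    covariates <- pheno[object$covariate_cols]
  }
  cfg <- object$config
  probs <- matrix(0, nrow(expr), length(object$records))
  for (k in seq_along(object$records)) {
    r <- object$records[[k]]
    di <- object$train_expr$sample_id %in% r$density_ids
    feats <- logratio_features(
      object$train_expr[di, , drop = FALSE], object$train_labels[di], expr,
      pairs = object$pairs, bandwidth_scale = cfg$bandwidth_scale,
      density_floor = cfg$density_floor
    )
    probs[, k] <- predict(r$fit, feats, covariates = covariates)
  }
  tibble::tibble(sample_id = expr$sample_id, probability = rowMeans(probs))
}

#' Tidy the per-pair selection weights of a fitted model
#'
#' Broom-style accessor: one row per gene pair with the selection weight
#' (number of splits selecting the pair) and the mean absolute coefficient
#' across selecting splits.
#'
#' @param x A `jdinac_fit`.
#' @param ... Unused.
#' @return Tibble `gene_a`, `gene_b`, `weight`, `mean_abs_coef`, sorted by
#'   descending weight, then descending `mean_abs_coef`, then pair name.
#' @method tidy jdinac_fit
#' @export
tidy.jdinac_fit <- function(x, ...) {
  dplyr::arrange(
    x$weights,
    dplyr::desc(.data$weight), dplyr::desc(.data$mean_abs_coef),
    .data$gene_a, .data$gene_b
  )
}

#' One-row model summary
#'
#' @param x A `jdinac_fit`.
#' @param ... Unused.
#' @return Tibble with split count, pair universe size, number of
#'   ever-selected pairs and training size.
#' @method glance jdinac_fit
#' @export
glance.jdinac_fit <- function(x, ...) {
  tibble::tibble(
    n_splits = x$n_splits,
    n_pairs = nrow(x$pairs),
    n_selected_pairs = sum(x$weights$weight > 0),
    n_train = nrow(x$train_expr),
    n_genes = length(x$genes)
  )
}

#' @export
print.jdinac_fit <- function(x, ...) {
  g <- glance(x)
  cat(sprintf(
    "pairwise density-ratio classifier: %d genes, %d pairs, H = %d splits; %d pairs ever selected\n",
    g$n_genes, g$n_pairs, g$n_splits, g$n_selected_pairs
  ))
  invisible(x)
}

#' @importFrom generics tidy
#' @export
generics::tidy

#' @importFrom generics glance
#' @export
generics::glance
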