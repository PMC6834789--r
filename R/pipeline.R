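# End-to-end orchestration: simulate or load data, filter, split, fit the
# pairwise classifier and baselines, predict, build the network, evaluate,
# and write every artifact to a directory. All randomness derives from one
# global seed, namespaced per stage, so adding a stage never perturbs the
# randomness of earlier ones.

default_config <- function() {
  list(
    seed = 1,
    simulation = list(
      enabled = TRUE, n_class0 = 172, n_class1 = 193, n_genes = 20,
      planted = NULL, background_rho = 0, zero_inflation = 0
    ),
    paths = list(expression = NULL, phenotype = NULL),
    preprocess = list(
      max_zero_fraction = 0.30, transform = "none",
      n_train_pos = NULL, n_train_neg = NULL, train_fraction = 2 / 3
    ),
    jdinac = list(
      n_splits = 20, swap_roles = TRUE, bandwidth_scale = 1,
      density_floor = 1e-10, cv_folds = 5,
      covariate_cols = c("age", "sex", "educ")
    ),
    baselines = list(methods = c("rf", "plr"), n_trees = 500),
    network = list(min_weight = 1, min_degree = 5, k = 10),
    evaluation = list(threshold = 0.5, n_boot = 2000, alpha = 0.05)
  )
}

merge_config <- function(base, user) {
  for (nm in names(user)) {
    base[[nm]] <- if (is.list(user[[nm]]) && is.list(base[[nm]])) {
      merge_config(base[[nm]], user[[nm]])
    } else {
      user[[nm]]
    }
  }
  base
}

#' Run the full analysis pipeline
#'
#' Orchestrates simulate/load, zero-fraction filtering, optional transform,
#' stratified train/test split, pairwise-classifier and baseline fits,
#' prediction, network construction, evaluation and the cohort table, and
#' writes every artifact (filtered matrix, split plan, weights, network,
#' predictions, JSON report with the config snapshot embedded) under
#' `out_dir`. Re-running with the same configuration reproduces identical
#' payloads.
#'
#' @param config A nested list, or a path to a YAML/JSON file with the same
#'   schema (see [read_config()]); unspecified entries take defaults.
#' @param out_dir Output directory, created if needed.
#' @return Invisibly, a list with all in-memory results (`data`, `split`,
#'   `fits`, `predictions`, `network`, `hubs`, `top_pairs`, `report`,
#'   `cohort`, `config`).
#' @export
run_pipeline <- function(config = list(), out_dir = tempfile("jdinac_run")) {
  if (is.character(config)) config <- read_config(config)
  cfg <- merge_config(default_config(), config)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  seed <- cfg$seed

  # -- data ----------------------------------------------------------------
  if (isTRUE(cfg$simulation$enabled)) {
    sm <- cfg$simulation
    planted <- if (is.null(sm$planted)) NULL else {
      planted_pairs(
        sm$planted$gene_a, sm$planted$gene_b,
        rho0 = sm$planted$rho0, rho1 = sm$planted$rho1,
        nonlinear = sm$planted$nonlinear %||% FALSE
      )
    }
    sim <- simulate_dataset(
      n_class0 = sm$n_class0, n_class1 = sm$n_class1, n_genes = sm$n_genes,
      planted_pairs = planted, background_rho = sm$background_rho,
      zero_inflation = sm$zero_inflation,
      seed = stage_seed(seed, "simulate")
    )
    expr <- sim$expression
    pheno <- sim$phenotype
    if (nrow(sim$truth) > 0) write_table(sim$truth, file.path(out_dir, "truth_pairs.tsv"))
  } else {
    if (is.null(cfg$paths$expression) || !file.exists(cfg$paths$expression)) {
      abort("config paths$expression is missing or does not exist")
    }
    if (is.null(cfg$paths$phenotype) || !file.exists(cfg$paths$phenotype)) {
      abort("config paths$phenotype is missing or does not exist")
    }
    expr <- read_expression(cfg$paths$expression)
    ph_cfg <- cfg$paths
    pheno <- read_phenotype(
      cfg$paths$phenotype,
      label_column = ph_cfg$label_column %||% "label",
      positive_label = ph_cfg$positive_label %||% "1",
      covariate_columns = ph_cfg$covariate_columns %||% character()
    )
  }
  pheno <- align_phenotype(expr, pheno)

  # -- preprocess ----------------------------------------------------------
  pp <- cfg$preprocess
  expr <- filter_zero_genes(expr, max_zero_fraction = pp$max_zero_fraction)
  removed <- attr(expr, "removed_genes")
  expr <- transform_expression(expr, mode = pp$transform)
  n_pos <- pp$n_train_pos %||% floor(sum(pheno$label == 1) * pp$train_fraction)
  n_neg <- pp$n_train_neg %||% floor(sum(pheno$label == 0) * pp$train_fraction)
  plan <- stratified_split(pheno, n_pos, n_neg, seed = stage_seed(seed, "split"))
  tr <- expr$sample_id %in% train_ids(plan)
  expr_tr <- expr[tr, , drop = FALSE]
  expr_te <- expr[!tr, , drop = FALSE]
  write_table(expr, file.path(out_dir, "expression_filtered.tsv"))
  write_table(plan, file.path(out_dir, "split_plan.tsv"))

  # -- models --------------------------------------------------------------
  jc <- cfg$jdinac
  covs <- intersect(jc$covariate_cols, names(pheno))
  fit <- jdinac(expr_tr, pheno,
    covariate_cols = if (length(covs)) covs else NULL,
    n_splits = jc$n_splits, swap_roles = jc$swap_roles,
    bandwidth_scale = jc$bandwidth_scale, density_floor = jc$density_floor,
    cv_folds = jc$cv_folds, seed = stage_seed(seed, "jdinac")
  )
  fits <- list(jdinac = fit)
  for (m in cfg$baselines$methods) {
    fits[[m]] <- fit_baseline(expr_tr, pheno,
      method = m,
      n_trees = cfg$baselines$n_trees,
      seed = stage_seed(seed, paste0("baseline_", m))
    )
  }

  predictions <- purrr::imap(fits, function(f, nm) {
    predict(f, expr_te, pheno = pheno)
  })
  for (nm in names(predictions)) {
    write_predictions(
      predictions[[nm]], file.path(out_dir, paste0("predictions_", nm, ".tsv")),
      threshold = cfg$evaluation$threshold
    )
  }
  write_table(tidy(fit), file.path(out_dir, "pair_weights.tsv"))

  # -- network -------------------------------------------------------------
  net <- build_network(fit, min_weight = cfg$network$min_weight)
  hubs <- hub_genes(net, min_degree = cfg$network$min_degree)
  top <- top_pairs(fit, k = min(cfg$network$k, max(sum(fit$weights$weight > 0), 1)))
  write_network(net, file.path(out_dir, "network.tsv"))
  write_table(hubs, file.path(out_dir, "hub_genes.tsv"))

  # -- evaluation ----------------------------------------------------------
  ev <- cfg$evaluation
  report <- evaluate_predictions(predictions, pheno,
    threshold = ev$threshold, n_boot = ev$n_boot, alpha = ev$alpha,
    seed = stage_seed(seed, "bootstrap")
  )
  cohort <- cohort_table(pheno)
  full_report <- list(
    config = cfg,
    removed_genes = removed,
    n_train = sum(tr), n_test = sum(!tr),
    network = list(
      n_edges = nrow(net), min_weight = cfg$network$min_weight,
      hubs = hubs, top_pairs = top
    ),
    cohort_table = cohort,
    metrics = report$metrics,
    delong = report$delong,
    bootstrap = report$settings
  )
  write_report(full_report, file.path(out_dir, "report.json"))
  write_table(report$roc, file.path(out_dir, "roc_points.tsv"))
  write_table(cohort, file.path(out_dir, "cohort_table.tsv"))

  invisible(list(
    data = list(expression = expr, phenotype = pheno),
    split = plan, fits = fits, predictions = predictions,
    network = net, hubs = hubs, top_pairs = top,
    report = report, cohort = cohort, config = cfg, out_dir = out_dir
  ))
}
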