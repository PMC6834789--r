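# Synthetic two-class expression data with planted differential pairwise
# dependence. The generator is the ground-truth test bed for the whole
# pipeline: class labels carry no marginal expression signal unless asked
# for, so any classification signal comes from the planted pair structure.

#' Declare planted differential gene pairs
#'
#' Convenience constructor for the `planted_pairs` argument of
#' [simulate_dataset()]. Each row plants one gene pair with within-pair
#' Pearson correlation `rho0` in class 0 and `rho1` in class 1; a pair with
#' `rho0 != rho1` (or `nonlinear = TRUE`) is differential and enters the
#' truth set.
#'
#' @param gene_a,gene_b Integer gene indices (1-based).
#' @param rho0,rho1 Within-pair correlation per class, each in (-1, 1).
#' @param nonlinear If `TRUE`, class 1 replaces the linear dependence by a
#'   quadratic one (gene_b is driven by gene_a squared), giving a pair whose
#'   class-1 association is strong but has near-zero linear correlation.
#' @return Tibble understood by [simulate_dataset()].
#' @export
planted_pairs <- function(gene_a, gene_b, rho0 = 0, rho1 = 0, nonlinear = FALSE) {
  tibble::tibble(
    gene_a = as.integer(gene_a), gene_b = as.integer(gene_b),
    rho0 = rho0, rho1 = rho1, nonlinear = nonlinear
  )
}

default_confounders <- function() {
  # Cohort-scale demographics: age at death, years of education (means/SDs
  # per diagnostic class) and sex as a per-class proportion. Class 1 is the
  # case group.
  list(
    age = list(type = "continuous", mean = c(84.60, 88.29), sd = c(5.32, 3.08)),
    sex = list(type = "binary", prob = c(0.599, 0.689)),
    educ = list(type = "continuous", mean = c(16.48, 16.54), sd = c(3.43, 3.42))
  )
}

build_corr <- function(n_genes, pairs, background_rho, which_rho) {
  S <- matrix(background_rho, n_genes, n_genes)
  diag(S) <- 1
  if (nrow(pairs) > 0) {
    for (k in seq_len(nrow(pairs))) {
      r <- pairs[[which_rho]][k]
      S[pairs$gene_a[k], pairs$gene_b[k]] <- r
      S[pairs$gene_b[k], pairs$gene_a[k]] <- r
    }
  }
  S
}

ensure_pd <- function(S, tol = 0.1) {
  ev <- eigen(S, symmetric = TRUE, only.values = TRUE)$values
  if (min(ev) > 1e-8) return(S)
  rep <- as.matrix(Matrix::nearPD(S, corr = TRUE)$mat)
  if (max(abs(rep - S)) > tol) {
    abort("correlation matrix is not positive definite and cannot be repaired within tolerance")
  }
  inform("correlation matrix repaired to nearest positive definite")
  rep
}

#' Emulate cohort demographics
#'
#' Draws a per-sample covariate table whose per-class sample moments
#' converge to the configured means, SDs and proportions as n grows.
#' Defaults emulate an elderly autopsy cohort (age at death, years of
#' education, sex) with the case class slightly older and more often female.
#'
#' @param n_class0,n_class1 Samples per class (class 1 = cases).
#' @param confounders Named list; each element has `type = "continuous"`
#'   with `mean`/`sd` length-2 vectors `(class0, class1)`, or
#'   `type = "binary"` with `prob` likewise.
#' @param seed Integer seed; the draw is reproducible given the seed.
#' @param id_prefix Prefix for generated sample identifiers.
#' @return Phenotype tibble (`sample_id`, `label`, one column per covariate).
#' @export
simulate_demographics <- function(n_class0, n_class1,
                                  confounders = default_confounders(),
                                  seed = NULL, id_prefix = "s") {
  stopifnot(n_class0 >= 0, n_class1 >= 0)
  for (cv in confounders) {
    if (cv$type == "binary" && any(cv$prob < 0 | cv$prob > 1)) {
      abort("binary confounder proportions must lie in [0, 1]")
    }
  }
  draw <- function() {
    n <- n_class0 + n_class1
    out <- tibble::tibble(
      sample_id = sprintf("%s%03d", id_prefix, seq_len(n)),
      label = rep(c(0L, 1L), c(n_class0, n_class1))
    )
    for (nm in names(confounders)) {
      cv <- confounders[[nm]]
      out[[nm]] <- if (cv$type == "binary") {
        rbinom(n, 1, cv$prob[out$label + 1])
      } else {
        rnorm(n, cv$mean[out$label + 1], cv$sd[out$label + 1])
      }
    }
    out
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Simulate a two-class expression dataset with planted differential pairs
#'
#' Per class, samples are drawn from a multivariate normal whose correlation
#' matrix embeds the class-specific `rho` of every planted pair and
#' `background_rho` elsewhere (repaired to the nearest positive-definite
#' correlation matrix if needed). Marginal mean shifts, confounder draws and
#' zero-inflation are applied afterwards, in that order, so the dependence
#' target stays interpretable. With all `rho0 == rho1` and zero marginal
#' effects the dataset carries no class signal by construction.
#'
#' @inheritParams simulate_demographics
#' @param n_genes Number of genes.
#' @param planted_pairs Tibble from [planted_pairs()], or `NULL` for none.
#' @param background_rho Correlation for all non-planted pairs.
#' @param marginal_effects Per-gene mean shift added to class 1 (scalar or
#'   length `n_genes`; default 0, i.e. no single-gene signal).
#' @param zero_inflation Per-gene probability that a value is replaced by
#'   exactly 0 (scalar or length `n_genes`).
#' @param allow_shared_genes Planted pairs sharing a gene are rejected
#'   unless this is `TRUE` (sharing creates hub structure deliberately).
#' @param seed Integer seed; identical seeds give identical datasets.
#' @return List with `expression` (tibble), `phenotype` (tibble) and
#'   `truth` (tibble of differential pairs by gene name).
#' @examples
#' sim <- simulate_dataset(
#'   n_class0 = 50, n_class1 = 50, n_genes = 6,
#'   planted_pairs = planted_pairs(1, 2, rho0 = 0, rho1 = 0.8), seed = 1
#' )
#' sim$truth
#' @export
simulate_dataset <- function(n_class0 = 172, n_class1 = 193, n_genes = 171,
                             planted_pairs = NULL, background_rho = 0,
                             marginal_effects = 0, zero_inflation = 0,
                             confounders = default_confounders(),
                             allow_shared_genes = FALSE, seed = NULL,
                             id_prefix = "s") {
  stopifnot(n_class0 >= 2, n_class1 >= 2, n_genes >= 1)
  pairs <- planted_pairs %||% planted_pairs(integer(), integer())
  if (nrow(pairs) > 0) {
    stopifnot(
      all(pairs$gene_a >= 1), all(pairs$gene_b <= n_genes),
      all(pairs$gene_a != pairs$gene_b),
      all(abs(pairs$rho0) < 1), all(abs(pairs$rho1) < 1)
    )
    shared <- anyDuplicated(c(pairs$gene_a, pairs$gene_b)) > 0
    if (shared && !allow_shared_genes) {
      abort("planted pairs share genes; set allow_shared_genes = TRUE if intended")
    }
  }
  stopifnot(abs(background_rho) < 1)
  marginal_effects <- rep_len(marginal_effects, n_genes)
  zero_inflation <- rep_len(zero_inflation, n_genes)
  stopifnot(all(zero_inflation >= 0), all(zero_inflation <= 1))

  S0 <- ensure_pd(build_corr(n_genes, pairs, background_rho, "rho0"))
  S1 <- ensure_pd(build_corr(n_genes, pairs, background_rho, "rho1"))

  draw <- function() {
    x0 <- MASS::mvrnorm(n_class0, mu = rep(0, n_genes), Sigma = S0)
    x1 <- MASS::mvrnorm(n_class1, mu = marginal_effects, Sigma = S1)
    nl <- pairs[pairs$nonlinear, , drop = FALSE]
    if (nrow(nl) > 0) {
      # Quadratic dependence in class 1: gene_b tracks gene_a^2. The driver
      # (x^2 - 1)/sqrt(2) is standardized for x ~ N(0,1); mixing keeps the
      # marginal near-standard while the linear correlation stays ~0.
      for (k in seq_len(nrow(nl))) {
        a <- x1[, nl$gene_a[k]]
        x1[, nl$gene_b[k]] <-
          sqrt(0.8) * (a^2 - 1) / sqrt(2) + sqrt(0.2) * rnorm(n_class1)
      }
    }
    x <- rbind(x0, x1)
    mask <- matrix(
      rbinom(length(x), 1, rep(zero_inflation, each = nrow(x))),
      nrow = nrow(x)
    )
    x[mask == 1] <- 0
    pheno <- simulate_demographics(n_class0, n_class1,
      confounders = confounders, id_prefix = id_prefix
    )
    colnames(x) <- sprintf("G%03d", seq_len(n_genes))
    rownames(x) <- pheno$sample_id
    list(x = x, pheno = pheno)
  }
  d <- if (is.null(seed)) draw() else withr::with_seed(seed, draw())

  gene_names <- colnames(d$x)
  diff <- pairs[pairs$rho0 != pairs$rho1 | pairs$nonlinear, , drop = FALSE]
  truth <- tibble::tibble(
    gene_a = pmin(gene_names[diff$gene_a], gene_names[diff$gene_b]),
    gene_b = pmax(gene_names[diff$gene_a], gene_names[diff$gene_b])
  )
  list(
    expression = matrix_to_expr(d$x),
    phenotype = d$pheno,
    truth = truth
  )
}
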