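# Study-design preprocessing: zero-fraction gene filtering, stratified
# train/test splitting, optional expression transforms.

#' Filter genes by zero-expression fraction
#'
#' Removes every gene whose fraction of exactly-zero values is strictly
#' greater than `max_zero_fraction`; a gene sitting exactly on the boundary
#' is retained. The removed genes are recorded in the `removed_genes`
#' attribute and messaged.
#'
#' @param expr Expression tibble (`sample_id` + gene columns).
#' @param max_zero_fraction Removal threshold as a proportion; default 0.30.
#' @return The filtered expression tibble, with attribute `removed_genes`.
#' @export
filter_zero_genes <- function(expr, max_zero_fraction = 0.30) {
  m <- expr_to_matrix(expr)
  zero_frac <- colMeans(m == 0)
  removed <- colnames(m)[zero_frac > max_zero_fraction]
  if (length(removed) == ncol(m)) {
    abort(sprintf(
      "all %d genes exceed a %.0f%% zero fraction; review the threshold",
      ncol(m), 100 * max_zero_fraction
    ))
  }
  if (length(removed) > 0) {
    inform(sprintf(
      "removed %d/%d genes with > %.0f%% zeros: %s",
      length(removed), ncol(m), 100 * max_zero_fraction,
      paste(head(removed, 10), collapse = ", ")
    ))
  }
  out <- expr[c("sample_id", setdiff(colnames(m), removed))]
  attr(out, "removed_genes") <- removed
  out
}

#' Stratified train/test split
#'
#' Draws the requested number of training samples uniformly at random
#' without replacement within each class; all remaining samples form the
#' test set. Sample ids are sorted before sampling so the plan depends only
#' on the id set and seed, never on file row order.
#'
#' @param pheno Phenotype tibble with `sample_id` and 0/1 `label`.
#' @param n_train_pos Training samples from class 1.
#' @param n_train_neg Training samples from class 0.
#' @param seed Integer seed; identical seeds give identical plans.
#' @return A `split_plan` tibble (`sample_id`, `role` in train/test) with
#'   helper accessors [train_ids()] / [test_ids()].
#' @examples
#' pheno <- tibble::tibble(
#'   sample_id = sprintf("s%03d", 1:365),
#'   label = rep(c(1L, 0L), c(193, 172))
#' )
#' plan <- stratified_split(pheno, n_train_pos = 135, n_train_neg = 120, seed = 1)
#' table(plan$role)
#' @export
stratified_split <- function(pheno, n_train_pos, n_train_neg, seed = NULL) {
  check_binary_label(pheno$label)
  pos <- sort(pheno$sample_id[pheno$label == 1])
  neg <- sort(pheno$sample_id[pheno$label == 0])
  if (n_train_pos > length(pos)) {
    abort(sprintf(
      "requested %d training cases but class 1 has only %d samples",
      n_train_pos, length(pos)
    ))
  }
  if (n_train_neg > length(neg)) {
    abort(sprintf(
      "requested %d training controls but class 0 has only %d samples",
      n_train_neg, length(neg)
    ))
  }
  pick <- function() {
    c(sample(pos, n_train_pos), sample(neg, n_train_neg))
  }
  train <- if (is.null(seed)) pick() else withr::with_seed(seed, pick())
  if (n_train_pos == length(pos) && n_train_neg == length(neg)) {
    warn("training set uses every sample; the test set is empty")
  }
  plan <- tibble::tibble(
    sample_id = pheno$sample_id,
    role = ifelse(pheno$sample_id %in% train, "train", "test")
  )
  class(plan) <- c("split_plan", class(plan))
  attr(plan, "seed") <- seed
  plan
}

#' @rdname stratified_split
#' @param plan A `split_plan`.
#' @export
train_ids <- function(plan) plan$sample_id[plan$role == "train"]

#' @rdname stratified_split
#' @export
test_ids <- function(plan) plan$sample_id[plan$role == "test"]

#' Transform expression values
#'
#' `log2p1` applies `log2(x + 1)` elementwise (non-negative input only);
#' `zscore` standardizes each gene to mean 0, SD 1; `none` is the identity.
#'
#' @param expr Expression tibble.
#' @param mode One of `"none"`, `"log2p1"`, `"zscore"`.
#' @return Transformed expression tibble.
#' @export
transform_expression <- function(expr, mode = c("none", "log2p1", "zscore")) {
  mode <- match.arg(mode)
  if (mode == "none") return(expr)
  m <- expr_to_matrix(expr)
  if (mode == "log2p1") {
    if (any(m < 0)) abort("log2p1 requires non-negative expression values")
    m <- log2(m + 1)
  } else {
    m <- scale(m)
    m[is.nan(m)] <- 0 # constant gene: leave centered at 0
    attr(m, "scaled:center") <- NULL
    attr(m, "scaled:scale") <- NULL
  }
  rownames(m) <- expr$sample_id
  matrix_to_expr(m)
}
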