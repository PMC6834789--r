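# Internal helpers shared across modules.

# Expression tibbles carry sample ids in `sample_id` and one numeric column
# per gene. These helpers move between that representation and a plain
# matrix with rownames.
expr_to_matrix <- function(expr) {
  stopifnot(is.data.frame(expr), "sample_id" %in% names(expr))
  genes <- setdiff(names(expr), "sample_id")
  m <- as.matrix(expr[genes])
  if (!is.numeric(m)) {
    abort("expression columns must all be numeric")
  }
  rownames(m) <- expr$sample_id
  m
}

matrix_to_expr <- function(m) {
  tibble::as_tibble(m, .name_repair = "minimal") |>
    dplyr::mutate(sample_id = rownames(m), .before = 1)
}

gene_ids <- function(expr) setdiff(names(expr), "sample_id")

# Check a phenotype table against an expression table and return the
# phenotype rows reordered to the expression sample order.
align_phenotype <- function(expr, pheno) {
  stopifnot("sample_id" %in% names(pheno))
  orphans <- setdiff(expr$sample_id, pheno$sample_id)
  if (length(orphans) > 0) {
    abort(paste0(
      "samples present in expression but absent from phenotype: ",
      paste(head(orphans, 10), collapse = ", "),
      if (length(orphans) > 10) sprintf(" (and %d more)", length(orphans) - 10) else ""
    ))
  }
  pheno[match(expr$sample_id, pheno$sample_id), , drop = FALSE]
}

check_binary_label <- function(label) {
  u <- sort(unique(label))
  if (!all(u %in% c(0, 1))) {
    abort("labels must be coded 0/1")
  }
  if (length(u) < 2) {
    abort("both classes must be present")
  }
  invisible(label)
}

# Deterministic per-stage seed derived from a global seed, so adding a
# pipeline stage never perturbs the randomness of earlier stages.
stage_seed <- function(seed, stage) {
  h <- sum(utf8ToInt(stage) * seq_along(utf8ToInt(stage)))
  as.integer((as.numeric(seed) * 7919 + h) %% 2147483647L)
}

# Unordered pair key with lexicographic orientation, used everywhere a
# gene pair must have one canonical name.
pair_key <- function(a, b) {
  paste(pmin(a, b), pmax(a, b), sep = "|")
}

all_pairs <- function(genes) {
  if (length(genes) < 2) {
    return(tibble::tibble(gene_a = character(), gene_b = character()))
  }
  idx <- utils::combn(length(genes), 2)
  tibble::tibble(
    gene_a = pmin(genes[idx[1, ]], genes[idx[2, ]]),
    gene_b = pmax(genes[idx[1, ]], genes[idx[2, ]])
  )
}
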