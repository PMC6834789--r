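# Class-conditional bivariate kernel density estimation and the
# log-density-ratio features that drive the pairwise classifier. The
# estimator is a product-Gaussian kernel with per-axis normal-reference
# bandwidths, evaluated as an exact kernel sum (no grid interpolation):
# pair dimensionality is 2 and n is in the hundreds, so exactness is cheap.

# Normal-reference bandwidth h = 1.06 * min(sd, IQR/1.34) * n^(-1/5),
# floored so that degenerate (zero-variance) axes still yield a proper
# density spike rather than an error.
bandwidth_nrd <- function(x, floor = 1e-6) {
  n <- length(x)
  spread <- min(sd(x), stats::IQR(x) / 1.34)
  h <- 1.06 * spread * n^(-1 / 5)
  if (!is.finite(h) || h < floor) {
    warn("zero-variance axis: bandwidth floored")
    h <- floor
  }
  h
}

#' Fit a bivariate kernel density estimate
#'
#' Gaussian product kernel with independent per-axis bandwidths chosen by
#' the normal-reference rule. The fitted object stores the training points;
#' evaluation is an exact kernel sum, so the density is non-negative
#' everywhere and integrates to 1 over the plane.
#'
#' @param u,v Numeric coordinate vectors of equal length (>= 2 points).
#' @param bandwidth_scale Multiplier applied to both automatic bandwidths.
#' @param bandwidth_floor Lower bound for each bandwidth.
#' @return A `bivariate_kde` object.
#' @examples
#' kde <- fit_kde2(rnorm(100), rnorm(100))
#' eval_kde2(kde, 0, 0)
#' @export
fit_kde2 <- function(u, v, bandwidth_scale = 1, bandwidth_floor = 1e-6) {
  stopifnot(length(u) == length(v))
  if (length(u) < 2) abort("at least 2 training points are required")
  h_u <- max(bandwidth_nrd(u, bandwidth_floor) * bandwidth_scale, bandwidth_floor)
  h_v <- max(bandwidth_nrd(v, bandwidth_floor) * bandwidth_scale, bandwidth_floor)
  structure(
    list(u = as.numeric(u), v = as.numeric(v), h = c(h_u, h_v)),
    class = "bivariate_kde"
  )
}

#' Evaluate a bivariate KDE at query points
#'
#' Exact kernel-sum evaluation: for each query `(u, v)` the mean over
#' training points of the product of the two Gaussian kernels.
#'
#' @param kde A `bivariate_kde` from [fit_kde2()].
#' @param u,v Numeric query coordinate vectors of equal length.
#' @return Numeric vector of non-negative density values.
#' @export
eval_kde2 <- function(kde, u, v) {
  stopifnot(inherits(kde, "bivariate_kde"), length(u) == length(v))
  ku <- dnorm(outer(u, kde$u, "-") / kde$h[1]) / kde$h[1]
  kv <- dnorm(outer(v, kde$v, "-") / kde$h[2]) / kde$h[2]
  rowMeans(ku * kv)
}

#' @export
print.bivariate_kde <- function(x, ...) {
  cat(sprintf(
    "bivariate KDE: %d points, bandwidths (%.4g, %.4g)\n",
    length(x$u), x$h[1], x$h[2]
  ))
  invisible(x)
}

#' Log-density-ratio features for gene pairs
#'
#' For every gene pair (i, j), fits the class-1 and class-0 bivariate KDEs
#' on the density-estimation rows and evaluates
#' `ln(f1_ij(G_i, G_j) / f0_ij(G_i, G_j))` at every evaluation row. Both
#' densities are floored at `density_floor` before the log so features stay
#' finite far outside the training cloud. Swapping the class labels negates
#' every feature; identical class clouds give exactly zero features.
#'
#' @param expr_density Expression tibble used to fit the densities.
#' @param labels_density 0/1 vector aligned with `expr_density` rows.
#' @param expr_eval Expression tibble (same genes) at which features are
#'   computed.
#' @param pairs Tibble with `gene_a`, `gene_b` columns naming the pair
#'   universe; default all unordered pairs of the genes present.
#' @param bandwidth_scale,density_floor Density estimation controls; see
#'   [fit_kde2()].
#' @return Tibble: `sample_id` plus one numeric column per pair, named
#'   `"geneA|geneB"` with the pair lexicographically oriented.
#' @export
logratio_features <- function(expr_density, labels_density, expr_eval,
                              pairs = NULL, bandwidth_scale = 1,
                              density_floor = 1e-10) {
  check_binary_label(labels_density)
  md <- expr_to_matrix(expr_density)
  me <- expr_to_matrix(expr_eval)
  if (!identical(colnames(md), colnames(me))) {
    abort("density-part and evaluation-part gene columns must be identical")
  }
  if (sum(labels_density == 1) < 2 || sum(labels_density == 0) < 2) {
    abort("each class needs at least 2 density-estimation samples")
  }
  pairs <- pairs %||% all_pairs(colnames(md))
  missing <- setdiff(c(pairs$gene_a, pairs$gene_b), colnames(md))
  if (length(missing) > 0) {
    abort(paste0("pair genes absent from expression: ", paste(missing, collapse = ", ")))
  }
  i1 <- labels_density == 1
  i0 <- !i1
  # The per-axis kernel matrix K[eval, train] and its bandwidth depend only
  # on (gene, class), never on the partner gene, so they are shared across
  # all pairs touching a gene. Precomputing them makes the per-pair cost an
  # elementwise product + row mean; the result is identical to fitting
  # fit_kde2()/eval_kde2() pair by pair.
  kernel_cols <- function(rows) {
    lapply(setNames(colnames(md), colnames(md)), function(g) {
      h <- max(
        suppressWarnings(bandwidth_nrd(md[rows, g])) * bandwidth_scale, 1e-6
      )
      dnorm(outer(me[, g], md[rows, g], "-") / h) / h
    })
  }
  k1 <- kernel_cols(i1)
  k0 <- kernel_cols(i0)
  feats <- matrix(0, nrow(me), nrow(pairs))
  for (k in seq_len(nrow(pairs))) {
    a <- pairs$gene_a[k]
    b <- pairs$gene_b[k]
    f1 <- rowMeans(k1[[a]] * k1[[b]])
    f0 <- rowMeans(k0[[a]] * k0[[b]])
    feats[, k] <- log(pmax(f1, density_floor)) - log(pmax(f0, density_floor))
  }
  colnames(feats) <- pair_key(pairs$gene_a, pairs$gene_b)
  tibble::as_tibble(feats, .name_repair = "minimal") |>
    dplyr::mutate(sample_id = rownames(me), .before = 1)
}
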