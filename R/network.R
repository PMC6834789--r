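# Differential network construction from per-pair selection weights, hub
# extraction and top-pair ranking.

new_differential_network <- function(edges, min_weight = 1) {
  edges <- tibble::as_tibble(edges)
  edges$weight <- as.numeric(edges$weight)
  structure(
    dplyr::arrange(edges, dplyr::desc(.data$weight), .data$gene_a, .data$gene_b),
    class = c("differential_network", class(edges)),
    min_weight = min_weight
  )
}

#' Build the differential network from a fitted model
#'
#' An undirected edge joins every gene pair whose selection weight is at
#' least `min_weight`; genes with no retained edge do not appear as nodes.
#' Raising `min_weight` can only remove edges.
#'
#' @param fit A `jdinac_fit`.
#' @param min_weight Minimum selection weight for an edge (positive).
#' @return A `differential_network`: an edge tibble (`gene_a` < `gene_b`
#'   lexicographically, `weight`) sorted by descending weight then pair
#'   name, with the node set available via [network_nodes()].
#' @export
build_network <- function(fit, min_weight = 1) {
  stopifnot(min_weight > 0)
  w <- if (inherits(fit, "jdinac_fit")) fit$weights else tibble::as_tibble(fit)
  edges <- w |>
    dplyr::filter(.data$weight >= min_weight) |>
    dplyr::select("gene_a", "gene_b", "weight")
  new_differential_network(edges, min_weight = min_weight)
}

#' @rdname build_network
#' @param net A `differential_network`.
#' @export
network_nodes <- function(net) sort(unique(c(net$gene_a, net$gene_b)))

#' @export
print.differential_network <- function(x, ...) {
  cat(sprintf(
    "differential network: %d edges over %d genes (min weight %s)\n",
    nrow(x), length(network_nodes(x)), format(attr(x, "min_weight"))
  ))
  if (nrow(x) > 0) print(tibble::as_tibble(x), n = 5)
  invisible(x)
}

#' Hub genes of a differential network
#'
#' A hub is a gene with at least `min_degree` neighbours. Hubs are ordered
#' by total incident edge weight (descending), ties broken lexicographically.
#'
#' @param net A `differential_network`.
#' @param min_degree Minimum number of adjacent genes; default 5.
#' @return Tibble `gene`, `degree`, `incident_weight`, ordered as above.
#' @export
hub_genes <- function(net, min_degree = 5) {
  edges <- tibble::as_tibble(net)
  if (nrow(edges) == 0) {
    return(tibble::tibble(
      gene = character(), degree = integer(), incident_weight = double()
    ))
  }
  long <- dplyr::bind_rows(
    dplyr::select(edges, gene = "gene_a", "weight"),
    dplyr::select(edges, gene = "gene_b", "weight")
  )
  long |>
    dplyr::summarise(
      degree = dplyr::n(), incident_weight = sum(.data$weight),
      .by = "gene"
    ) |>
    dplyr::filter(.data$degree >= min_degree) |>
    dplyr::arrange(dplyr::desc(.data$incident_weight), .data$gene)
}

#' Top differential gene pairs
#'
#' The `k` pairs with the highest selection weight; ties broken by mean
#' absolute coefficient across selecting splits, then lexicographically.
#' Only pairs with positive weight are eligible; if fewer than `k` exist,
#' all are returned with a warning.
#'
#' @param fit A `jdinac_fit`.
#' @param k Number of pairs to return; default 10.
#' @return Tibble `rank`, `gene_a`, `gene_b`, `weight`, `mean_abs_coef`.
#' @export
top_pairs <- function(fit, k = 10) {
  ranked <- tidy(fit) |> dplyr::filter(.data$weight > 0)
  if (k > nrow(ranked)) {
    warn(sprintf(
      "requested %d pairs but only %d have positive weight", k, nrow(ranked)
    ))
    k <- nrow(ranked)
  }
  head(ranked, k) |> dplyr::mutate(rank = dplyr::row_number(), .before = 1)
}

#' Plot a differential network
#'
#' Circular layout with edge width proportional to selection weight and
#' hub genes highlighted.
#'
#' @param object A `differential_network`.
#' @param min_degree Hub highlight threshold (see [hub_genes()]).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.differential_network <- function(object, min_degree = 5, ...) {
  nodes <- network_nodes(object)
  if (length(nodes) == 0) {
    return(ggplot2::ggplot() +
      ggplot2::annotate("text", 0, 0, label = "empty network") +
      ggplot2::theme_void())
  }
  theta <- seq(0, 2 * pi, length.out = length(nodes) + 1)[seq_along(nodes)]
  layout <- tibble::tibble(gene = nodes, x = cos(theta), y = sin(theta))
  hubs <- hub_genes(object, min_degree = min_degree)$gene
  layout$hub <- layout$gene %in% hubs
  edges <- tibble::as_tibble(object) |>
    dplyr::left_join(dplyr::rename(layout[1:3], xa = "x", ya = "y"),
      by = c(gene_a = "gene")
    ) |>
    dplyr::left_join(dplyr::rename(layout[1:3], xb = "x", yb = "y"),
      by = c(gene_b = "gene")
    )
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(
        x = .data$xa, y = .data$ya, xend = .data$xb, yend = .data$yb,
        linewidth = .data$weight
      ),
      colour = "grey60", alpha = 0.7
    ) +
    ggplot2::geom_point(
      data = layout,
      ggplot2::aes(.data$x, .data$y, colour = .data$hub), size = 3
    ) +
    ggplot2::geom_text(
      data = layout,
      ggplot2::aes(.data$x * 1.12, .data$y * 1.12, label = .data$gene),
      size = 3
    ) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "steelblue"),
      labels = c(`TRUE` = "hub", `FALSE` = "gene"), name = NULL
    ) +
    ggplot2::scale_linewidth(range = c(0.2, 1.6), name = "weight") +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
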