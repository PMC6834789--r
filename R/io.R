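# Readers and writers for the package's external artifacts: expression
# matrices, phenotype tables, gene lists, network edge lists, prediction
# tables and evaluation reports.

detect_delim <- function(path, delim = NULL) {
  if (!is.null(delim)) return(delim)
  if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
}

#' Read a gene expression matrix
#'
#' Reads a delimited text file with one header row of identifiers and one
#' identifier column, and returns a tibble in samples-by-genes orientation
#' (a `sample_id` column followed by one numeric column per gene) regardless
#' of how the file is oriented on disk.
#'
#' @param path Path to a TSV/CSV file. The delimiter is inferred from the
#'   extension (`.csv` is comma, anything else tab) unless `delim` is given.
#' @param orientation Either `"samples_by_genes"` (rows are samples) or
#'   `"genes_by_samples"` (rows are genes; the result is transposed).
#' @param delim Optional explicit field delimiter.
#' @return A tibble with a `sample_id` column and one numeric column per gene.
#' @examples
#' f <- tempfile(fileext = ".tsv")
#' writeLines(c("id\tG1\tG2", "s1\t1\t2", "s2\t3\t4"), f)
#' read_expression(f)
#' @export
read_expression <- function(path,
                            orientation = c("samples_by_genes", "genes_by_samples"),
                            delim = NULL) {
  orientation <- match.arg(orientation)
  raw <- readr::read_delim(path,
    delim = detect_delim(path, delim),
    col_types = readr::cols(.default = readr::col_character()),
    name_repair = "minimal", progress = FALSE
  )
  header <- names(raw)
  if (anyDuplicated(header[-1])) {
    dups <- unique(header[-1][duplicated(header[-1])])
    abort(paste0("duplicate column identifiers: ", paste(dups, collapse = ", ")))
  }
  row_ids <- raw[[1]]
  if (anyDuplicated(row_ids)) {
    dups <- unique(row_ids[duplicated(row_ids)])
    abort(paste0("duplicate row identifiers: ", paste(dups, collapse = ", ")))
  }
  cells <- as.matrix(raw[-1])
  num <- suppressWarnings(matrix(as.numeric(cells), nrow = nrow(cells)))
  if (anyNA(num)) {
    bad <- which(is.na(num), arr.ind = TRUE)[1, ]
    abort(sprintf(
      "non-numeric or missing value at row '%s', column '%s'",
      row_ids[bad[1]], header[-1][bad[2]]
    ))
  }
  dimnames(num) <- list(row_ids, header[-1])
  if (orientation == "genes_by_samples") num <- t(num)
  matrix_to_expr(num)
}

#' Read a phenotype / covariate table
#'
#' Loads per-sample diagnosis labels and confounder covariates. The label
#' column is mapped to 1 for `positive_label` and 0 otherwise; categorical
#' covariates (e.g. sex) are converted to numeric through an explicit
#' user-supplied mapping -- no coding is ever guessed.
#'
#' @param path Path to a TSV/CSV file with a sample-identifier column.
#' @param label_column Name of the diagnosis column.
#' @param positive_label Value of `label_column` coded as 1 (the case class).
#' @param covariate_columns Character vector of covariate column names.
#' @param sample_column Name of the sample-identifier column; defaults to the
#'   first column of the file.
#' @param mappings Named list of named numeric vectors used to recode string
#'   covariates, e.g. `list(sex = c(female = 1, male = 0))`.
#' @param delim Optional explicit field delimiter.
#' @return A tibble with columns `sample_id`, `label` (0/1) and one numeric
#'   column per covariate.
#' @export
read_phenotype <- function(path, label_column, positive_label,
                           covariate_columns = character(),
                           sample_column = NULL, mappings = list(),
                           delim = NULL) {
  raw <- readr::read_delim(path,
    delim = detect_delim(path, delim),
    col_types = readr::cols(.default = readr::col_character()),
    progress = FALSE
  )
  sample_column <- sample_column %||% names(raw)[1]
  for (col in c(sample_column, label_column, covariate_columns)) {
    if (!col %in% names(raw)) abort(paste0("column not found: ", col))
  }
  labels_raw <- raw[[label_column]]
  if (length(unique(labels_raw)) > 2) {
    abort(sprintf(
      "label column '%s' has %d distinct values; expected at most 2",
      label_column, length(unique(labels_raw))
    ))
  }
  out <- tibble::tibble(
    sample_id = raw[[sample_column]],
    label = as.integer(labels_raw == positive_label)
  )
  if (anyDuplicated(out$sample_id)) {
    abort("duplicate sample identifiers in phenotype table")
  }
  for (col in covariate_columns) {
    vals <- raw[[col]]
    if (col %in% names(mappings)) {
      mapped <- unname(mappings[[col]][vals])
      if (anyNA(mapped)) {
        bad <- vals[which(is.na(mapped))[1]]
        abort(sprintf("covariate '%s': value '%s' missing from mapping", col, bad))
      }
      out[[col]] <- mapped
    } else {
      num <- suppressWarnings(as.numeric(vals))
      if (anyNA(num)) {
        i <- which(is.na(num))[1]
        abort(sprintf(
          "covariate '%s': non-numeric value '%s' for sample '%s'",
          col, vals[i], out$sample_id[i]
        ))
      }
      out[[col]] <- num
    }
  }
  out
}

#' Read a candidate gene list
#'
#' One identifier per line; blank lines and `#` comments are skipped.
#'
#' @param path Path to a plain-text file.
#' @return Character vector of gene identifiers.
#' @export
read_gene_list <- function(path) {
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- trimws(sub("#.*$", "", lines))
  lines[nzchar(lines)]
}

#' Write / read a differential network edge list
#'
#' The network is stored as a three-column TSV (`gene_a`, `gene_b`,
#' `weight`) sorted by descending weight and then lexicographically by pair,
#' so files are byte-stable for a given network.
#'
#' @param net A [differential_network] object (or any tibble with the three
#'   edge columns).
#' @param path Output file path.
#' @return `write_network` returns `path` invisibly; `read_network` returns
#'   a `differential_network`.
#' @export
write_network <- function(net, path) {
  edges <- tibble::as_tibble(net)[c("gene_a", "gene_b", "weight")] |>
    dplyr::arrange(dplyr::desc(.data$weight), .data$gene_a, .data$gene_b)
  readr::write_tsv(edges, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_network
#' @export
read_network <- function(path) {
  edges <- readr::read_tsv(path,
    col_types = readr::cols(
      gene_a = readr::col_character(),
      gene_b = readr::col_character(),
      weight = readr::col_double()
    ), progress = FALSE
  )
  new_differential_network(edges, min_weight = if (nrow(edges)) min(edges$weight) else 1)
}

#' Write / read per-sample predictions
#'
#' Predictions are stored as a TSV with columns `sample_id`, `probability`
#' and `predicted_class` (thresholded at `threshold`).
#'
#' @param preds Tibble with `sample_id` and `probability` columns.
#' @param path Output file path.
#' @param threshold Probability cutoff for the hard class call.
#' @return `write_predictions` returns `path` invisibly; `read_predictions`
#'   returns the tibble.
#' @export
write_predictions <- function(preds, path, threshold = 0.5) {
  out <- tibble::tibble(
    sample_id = preds$sample_id,
    probability = preds$probability,
    predicted_class = as.integer(preds$probability >= threshold)
  )
  readr::write_tsv(out, path, progress = FALSE)
  invisible(path)
}

#' @rdname write_predictions
#' @export
read_predictions <- function(path) {
  readr::read_tsv(path,
    col_types = readr::cols(
      sample_id = readr::col_character(),
      probability = readr::col_double(),
      predicted_class = readr::col_integer()
    ), progress = FALSE
  )
}

#' Write an evaluation report as JSON
#'
#' Serializes an [evaluate_predictions()] report (all metrics with their
#' confidence intervals, ROC points, DeLong comparisons and settings) to a
#' structured JSON document.
#'
#' @param report An `evaluation_report` object or a plain list.
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_report <- function(report, path) {
  jsonlite::write_json(unclass(report), path,
    auto_unbox = TRUE, digits = NA, pretty = TRUE, null = "null"
  )
  invisible(path)
}

#' Write expression / phenotype tables
#'
#' Plain delimited writers matching [read_expression()] / [read_phenotype()];
#' the delimiter follows the file extension.
#'
#' @param x Tibble to write.
#' @param path Output file path.
#' @param delim Optional explicit delimiter.
#' @return `path`, invisibly.
#' @export
write_table <- function(x, path, delim = NULL) {
  readr::write_delim(x, path, delim = detect_delim(path, delim), progress = FALSE)
  invisible(path)
}

#' Read a pipeline configuration file
#'
#' YAML and JSON configurations share one schema; the format is chosen by
#' file extension.
#'
#' @param path Path to a `.yaml`/`.yml` or `.json` file.
#' @return Nested named list.
#' @export
read_config <- function(path) {
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
}
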