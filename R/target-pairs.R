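#' Read a miRNA-to-gene target-prediction table
#'
#' A TargetScan-style static table of putative miRNA -> gene targeting pairs,
#' used to restrict which correlations the network stage tests. TSV with
#' columns `mirna_id` and `gene_id`; duplicate pairs and empty ids are
#' rejected.
#'
#' @param path Path to a TSV file.
#' @return A tibble with columns `mirna_id`, `gene_id`.
#' @export
read_target_pairs <- function(path) {
  if (!file.exists(path)) stopf("target-pair file not found: %s", path)
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE)
  missing <- setdiff(c("mirna_id", "gene_id"), names(df))
  if (length(missing) > 0) {
    stopf("target-pair table is missing column(s): %s",
          paste(missing, collapse = ", "), class = "stratomir_format_error")
  }
  df <- df[, c("mirna_id", "gene_id")]
  validate_target_pairs(df)
}

#' @rdname read_target_pairs
#' @param pairs A data frame with columns `mirna_id`, `gene_id`.
#' @export
validate_target_pairs <- function(pairs) {
  pairs <- tibble::as_tibble(pairs)
  if (any(is.na(pairs$mirna_id)) || any(is.na(pairs$gene_id)) ||
      any(!nzchar(pairs$mirna_id)) || any(!nzchar(pairs$gene_id))) {
    stopf("target-pair table contains empty or missing ids",
          class = "stratomir_format_error")
  }
  if (anyDuplicated(pairs[, c("mirna_id", "gene_id")])) {
    stopf("target-pair table contains duplicate pairs",
          class = "stratomir_format_error")
  }
  pairs
}

#' Write a target-prediction table
#'
#' @param pairs A valid pair table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_target_pairs <- function(pairs, path) {
  pairs <- validate_target_pairs(pairs)
  readr::write_tsv(pairs, path, progress = FALSE)
  invisible(path)
}

edge_tsv_columns <- c("mirna_id", "gene_id", "rho", "p", "n",
                      "mirna_log2fc", "gene_log2fc", "regulation_class")

#' Write a classified interaction edge list
#'
#' `format = "tsv"` writes every edge field (correlation, p-value, sample
#' count, both fold changes, regulation class) and round-trips through
#' [read_edges()]. `format = "sif"` writes Cytoscape simple-interaction
#' lines `mirna <regulation_class> gene`.
#'
#' @param edges A classified edge tibble (see [classify_edges()]).
#' @param path Output path.
#' @param format `"tsv"` or `"sif"`.
#' @return `path`, invisibly.
#' @export
write_edges <- function(edges, path, format = c("tsv", "sif")) {
  if (!is.character(format) || !all(format %in% c("tsv", "sif"))) {
    stopf("unknown edge output format: %s", paste(format, collapse = ", "),
          class = "stratomir_usage_error")
  }
  format <- match.arg(format)
  edges <- tibble::as_tibble(edges)
  if (format == "sif") {
    lines <- sprintf("%s %s %s", edges$mirna_id, edges$regulation_class,
                     edges$gene_id)
    readr::write_lines(lines, path)
  } else {
    keep <- intersect(edge_tsv_columns, names(edges))
    readr::write_tsv(edges[, keep, drop = FALSE], path, progress = FALSE)
  }
  invisible(path)
}

#' Read an interaction edge list written by [write_edges()]
#'
#' @param path Path to an edge TSV.
#' @return An edge tibble.
#' @export
read_edges <- function(path) {
  if (!file.exists(path)) stopf("edge file not found: %s", path)
  readr::read_tsv(path, col_types = readr::cols(
    mirna_id = readr::col_character(),
    gene_id = readr::col_character(),
    regulation_class = readr::col_character(),
    n = readr::col_integer(),
    .default = readr::col_double()
  ), progress = FALSE, show_col_types = FALSE)
}
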