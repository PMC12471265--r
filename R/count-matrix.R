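#' Validate a count matrix
#'
#' A count matrix is a base integer matrix with features in rows and samples
#' in columns, unique non-empty dimnames, and finite nonnegative integer
#' entries. This is the raw input to filtering, normalization and the
#' differential-expression engine.
#'
#' @param counts A numeric matrix with rownames (feature ids) and colnames
#'   (sample ids).
#' @return `counts`, invisibly, as an integer-mode matrix.
#' @export
validate_count_matrix <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts)) {
    stopf("`counts` must be a numeric matrix", class = "stratomir_format_error")
  }
  fid <- rownames(counts)
  sid <- colnames(counts)
  if (is.null(fid) || is.null(sid) || any(!nzchar(fid)) || any(!nzchar(sid))) {
    stopf("`counts` must have non-empty feature rownames and sample colnames",
          class = "stratomir_format_error")
  }
  if (anyDuplicated(fid)) {
    stopf("duplicate feature ids: %s",
          paste(unique(fid[duplicated(fid)]), collapse = ", "),
          class = "stratomir_format_error")
  }
  if (anyDuplicated(sid)) {
    stopf("duplicate sample ids: %s",
          paste(unique(sid[duplicated(sid)]), collapse = ", "),
          class = "stratomir_format_error")
  }
  bad <- which(!is.finite(counts) | counts < 0 | counts != round(counts),
               arr.ind = TRUE)
  if (nrow(bad) > 0) {
    stopf("count matrix entry at feature '%s', sample '%s' is not a finite nonnegative integer (value: %s)",
          fid[bad[1, 1]], sid[bad[1, 2]],
          format(counts[bad[1, 1], bad[1, 2]]),
          class = "stratomir_format_error")
  }
  storage.mode(counts) <- "integer"
  invisible(counts)
}

#' Read a count matrix from a tab-separated file
#'
#' The expected layout follows the GEO series-matrix convention: first column
#' holds feature ids, the header row holds sample ids, and every other cell is
#' a nonnegative integer count. Row and column order are preserved. Files that
#' violate the count-matrix invariants (duplicate ids, negative or
#' non-integer entries, missing values) are rejected, never coerced.
#'
#' @param path Path to a TSV file.
#' @return An integer matrix (features x samples).
#' @export
read_count_matrix <- function(path) {
  if (!file.exists(path)) stopf("count matrix file not found: %s", path)
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE, name_repair = "minimal")
  if (ncol(df) < 2 || nrow(df) == 0) {
    stopf("count matrix file must have a feature-id column, at least one sample column and at least one feature row: %s",
          path, class = "stratomir_format_error")
  }
  ids <- df[[1]]
  raw <- as.matrix(df[, -1, drop = FALSE])
  m <- suppressWarnings(matrix(as.numeric(raw), nrow = nrow(raw),
                               dimnames = list(ids, colnames(raw))))
  if (anyNA(m)) {
    bad <- which(is.na(m), arr.ind = TRUE)[1, ]
    stopf("non-numeric or missing count at feature '%s', sample '%s'",
          ids[bad[1]], colnames(m)[bad[2]], class = "stratomir_format_error")
  }
  m <- validate_count_matrix(m)
  m
}

#' Write a count matrix to a tab-separated file
#'
#' Inverse of [read_count_matrix()]: `read_count_matrix(write_count_matrix(x))`
#' returns an identical matrix.
#'
#' @param counts A valid count matrix.
#' @param path Output path.
#' @param id_column Header name for the feature-id column.
#' @return `path`, invisibly.
#' @export
write_count_matrix <- function(counts, path, id_column = "feature_id") {
  counts <- validate_count_matrix(counts)
  df <- tibble::as_tibble(counts, rownames = id_column)
  readr::write_tsv(df, path, progress = FALSE)
  invisible(path)
}
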