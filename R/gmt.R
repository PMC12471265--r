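#' Read a gene-set collection in GMT format
#'
#' Standard Broad-dialect GMT: one set per line, tab-separated as
#' `name<TAB>description<TAB>member<TAB>member...`. Duplicate member ids
#' within a line are collapsed; duplicate set names across lines are an
#' error.
#'
#' @param path Path to a `.gmt` file.
#' @return A tibble with columns `set_name`, `description` and a list-column
#'   `genes` (character vectors of unique member ids).
#' @export
read_gmt <- function(path) {
  if (!file.exists(path)) stopf("GMT file not found: %s", path)
  lines <- readr::read_lines(path, progress = FALSE)
  lines <- lines[nzchar(lines)]
  if (length(lines) == 0) {
    stopf("GMT file has no gene sets: %s", path,
          class = "stratomir_format_error")
  }
  fields <- strsplit(lines, "\t", fixed = TRUE)
  nf <- lengths(fields)
  if (any(nf < 3)) {
    stopf("GMT line %d has fewer than 3 tab-separated fields",
          which(nf < 3)[1], class = "stratomir_format_error")
  }
  out <- tibble::tibble(
    set_name = vapply(fields, `[[`, character(1), 1L),
    description = vapply(fields, `[[`, character(1), 2L),
    genes = lapply(fields, function(f) unique(f[-(1:2)]))
  )
  if (anyDuplicated(out$set_name)) {
    stopf("duplicate gene-set name(s): %s",
          paste(unique(out$set_name[duplicated(out$set_name)]), collapse = ", "),
          class = "stratomir_format_error")
  }
  if (any(lengths(out$genes) == 0)) {
    stopf("gene set '%s' has no members",
          out$set_name[lengths(out$genes) == 0][1],
          class = "stratomir_format_error")
  }
  out
}

#' Write a gene-set collection in GMT format
#'
#' Inverse of [read_gmt()] on valid collections.
#'
#' @param genesets A tibble as returned by [read_gmt()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_gmt <- function(genesets, path) {
  stopifnot(all(c("set_name", "description", "genes") %in% names(genesets)))
  if (anyDuplicated(genesets$set_name)) {
    stopf("duplicate gene-set name(s) in collection",
          class = "stratomir_format_error")
  }
  lines <- vapply(seq_len(nrow(genesets)), function(i) {
    paste(c(genesets$set_name[i], genesets$description[i],
            unique(genesets$genes[[i]])), collapse = "\t")
  }, character(1))
  readr::write_lines(lines, path)
  invisible(path)
}
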