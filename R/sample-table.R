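#' Validate a sample annotation table
#'
#' Sample tables carry one row per sequenced library with the columns
#' `sample_id`, `patient_id`, `ancestry` (EA/AA), `bmi_class` (obese/lean),
#' `tissue` (tumor/normal) and `assay` (miRNA/mRNA). For the miRNA assay the
#' study design is paired: every patient must contribute exactly one tumor
#' and one adjacent-normal library unless `allow_unpaired = TRUE`.
#'
#' @param samples A data frame with the required columns.
#' @param allow_unpaired Skip the paired-design check for the miRNA assay.
#' @return The validated table as a tibble.
#' @export
validate_sample_table <- function(samples, allow_unpaired = FALSE) {
  required <- c("sample_id", "patient_id", "ancestry", "bmi_class",
                "tissue", "assay")
  missing <- setdiff(required, names(samples))
  if (length(missing) > 0) {
    stopf("sample table is missing required column(s): %s",
          paste(missing, collapse = ", "), class = "stratomir_format_error")
  }
  samples <- tibble::as_tibble(samples)
  if (nrow(samples) == 0) {
    stopf("sample table has no rows", class = "stratomir_format_error")
  }
  if (anyDuplicated(samples$sample_id)) {
    stopf("duplicate sample_id: %s",
          paste(unique(samples$sample_id[duplicated(samples$sample_id)]),
                collapse = ", "),
          class = "stratomir_format_error")
  }
  check_enum(samples$ancestry, ANCESTRY_LEVELS, "ancestry")
  check_enum(samples$bmi_class, BMI_LEVELS, "bmi_class")
  check_enum(samples$tissue, TISSUE_LEVELS, "tissue")
  check_enum(samples$assay, ASSAY_LEVELS, "assay")
  if (!allow_unpaired) {
    mi <- samples[samples$assay == "miRNA", , drop = FALSE]
    if (nrow(mi) > 0) {
      chk <- mi %>%
        dplyr::count(.data$patient_id, .data$tissue) %>%
        tidyr::pivot_wider(names_from = "tissue", values_from = "n",
                           values_fill = 0L)
      for (lev in TISSUE_LEVELS) if (!lev %in% names(chk)) chk[[lev]] <- 0L
      bad <- chk$patient_id[chk$tumor != 1L | chk$normal != 1L]
      if (length(bad) > 0) {
        stopf("miRNA assay is paired by design: patient(s) %s lack exactly one tumor and one normal sample (use allow_unpaired = TRUE to override)",
              paste(bad, collapse = ", "), class = "stratomir_format_error")
      }
    }
  }
  samples
}

#' Read a sample annotation table
#'
#' @inheritParams validate_sample_table
#' @param path Path to a TSV file with the required columns.
#' @return A validated tibble.
#' @export
read_sample_table <- function(path, allow_unpaired = FALSE) {
  if (!file.exists(path)) stopf("sample table file not found: %s", path)
  if (file.size(path) == 0) {
    stopf("sample table file is empty: %s", path,
          class = "stratomir_format_error")
  }
  df <- readr::read_tsv(path, col_types = readr::cols(
    .default = readr::col_character()
  ), progress = FALSE, show_col_types = FALSE)
  validate_sample_table(df, allow_unpaired = allow_unpaired)
}

#' Write a sample annotation table
#'
#' @param samples A valid sample table.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_sample_table <- function(samples, path) {
  samples <- validate_sample_table(samples, allow_unpaired = TRUE)
  readr::write_tsv(samples, path, progress = FALSE)
  invisible(path)
}
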