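#' Run the full study contrast set
#'
#' Executes the study's eight differential-expression comparisons:
#' miRNA tumor-vs-normal (paired by patient) for each ancestry at BMI strata
#' `both`, `obese` and `lean` (six tables, FDR + fold-change thresholds), and
#' mRNA obese-vs-lean on tumor samples for each ancestry (two tables, raw
#' p-value threshold). Direction conventions are tumor over normal and obese
#' over lean. Each assay's counts are low-count filtered and TMM-normalized
#' globally before any contrast runs; a contrast whose stratum is empty is
#' skipped with a warning.
#'
#' @param mirna_counts,mrna_counts Raw count matrices (`mrna_counts` may be
#'   NULL to run the miRNA contrasts only).
#' @param samples Sample table covering both assays.
#' @param mirna_thresholds,mrna_thresholds Named lists overriding the default
#'   call thresholds (miRNA: `fdr_max = 0.05`, `min_abs_log2fc = 1`;
#'   mRNA: raw `p_max = 0.05`).
#' @param min_count,min_fraction Low-count filter parameters.
#' @return A named list of `de_table` tibbles
#'   (`mirna_<ancestry>_<bmi>_tvn`, `mrna_<ancestry>_ovl`) with attributes
#'   `mirna_factors`, `mrna_factors`, `mirna_filtered`, `mrna_filtered`.
#' @export
run_study_contrasts <- function(mirna_counts, mrna_counts, samples,
                                mirna_thresholds = list(),
                                mrna_thresholds = list(),
                                min_count = 5, min_fraction = 0.8) {
  samples <- validate_sample_table(samples, allow_unpaired = TRUE)
  mi_th <- utils::modifyList(
    list(fdr_max = 0.05, min_abs_log2fc = 1, use_raw_p = FALSE, p_max = 0.05),
    mirna_thresholds)
  mr_th <- utils::modifyList(
    list(fdr_max = 0.05, min_abs_log2fc = 0, use_raw_p = TRUE, p_max = 0.05),
    mrna_thresholds)

  mirna_f <- filter_low_counts(mirna_counts, min_count, min_fraction)
  mirna_factors <- tmm_factors(mirna_f)
  out <- list()
  for (anc in ANCESTRY_LEVELS) {
    for (bmi in c("both", "obese", "lean")) {
      design <- de_design("miRNA", "tumor_vs_normal", ancestry = anc,
                          bmi_class = bmi, pairing = "paired_by_patient",
                          fdr_max = mi_th$fdr_max,
                          min_abs_log2fc = mi_th$min_abs_log2fc,
                          use_raw_p = mi_th$use_raw_p, p_max = mi_th$p_max)
      nm <- sprintf("mirna_%s_%s_tvn", anc, bmi)
      tab <- tryCatch(
        nb_wald_test(mirna_f, samples, design, mirna_factors),
        error = function(e) {
          warnf("skipping contrast %s: %s", nm, conditionMessage(e))
          NULL
        })
      if (!is.null(tab)) out[[nm]] <- tab
    }
  }

  mrna_factors <- NULL
  mrna_f <- NULL
  if (!is.null(mrna_counts)) {
    mrna_f <- filter_low_counts(mrna_counts, min_count, min_fraction)
    mrna_factors <- tmm_factors(mrna_f)
    for (anc in ANCESTRY_LEVELS) {
      design <- de_design("mRNA", "obese_vs_lean", ancestry = anc,
                          pairing = "unpaired",
                          fdr_max = mr_th$fdr_max,
                          min_abs_log2fc = mr_th$min_abs_log2fc,
                          use_raw_p = mr_th$use_raw_p, p_max = mr_th$p_max)
      nm <- sprintf("mrna_%s_ovl", anc)
      tab <- tryCatch(
        nb_wald_test(mrna_f, samples, design, mrna_factors),
        error = function(e) {
          warnf("skipping contrast %s: %s", nm, conditionMessage(e))
          NULL
        })
      if (!is.null(tab)) out[[nm]] <- tab
    }
  }
  attr(out, "mirna_factors") <- mirna_factors
  attr(out, "mrna_factors") <- mrna_factors
  attr(out, "mirna_filtered") <- mirna_f
  attr(out, "mrna_filtered") <- mrna_f
  out
}

#' DE feature ids from a table
#'
#' @param de A `de_table` or a character vector (returned unchanged).
#' @return Character vector of features with `is_de = TRUE`.
#' @export
de_features <- function(de) {
  if (is.character(de)) return(unique(de))
  stopifnot(is.data.frame(de), all(c("feature_id", "is_de") %in% names(de)))
  de$feature_id[de$is_de]
}
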