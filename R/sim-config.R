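#' Configuration for the synthetic study generator
#'
#' Describes a study-shaped dataset: 2 ancestries x 2 BMI classes x
#' `n_patients_per_cell` patients, each contributing a paired tumor and
#' adjacent-normal miRNA library (8 x `n_patients_per_cell` miRNA samples)
#' and a tumor-only mRNA library (4 x `n_patients_per_cell` mRNA samples).
#' Counts are negative-binomial with `variance = mu + phi * mu^2` and
#' log-normal per-sample library-size multipliers. Tumor-vs-normal miRNA
#' effects are planted per (ancestry, BMI) stratum on tumor samples only
#' (the adjacent-normal mean is the shared baseline, mirroring the paired
#' contrast); a shared-core block is planted in tumors of all four strata.
#' Obese-vs-lean mRNA effects are planted per ancestry on obese tumors.
#' True miRNA-target pairs repress the target at the mean level: the gene's
#' NB mean is multiplied by `2^(repression_strength * z)` where `z` is the
#' standardized abundance of the paired miRNA sample, producing a
#' controllable, sign-correct negative correlation.
#'
#' @param n_patients_per_cell Patients per (ancestry x BMI) cell (default 6,
#'   the study design).
#' @param n_mirnas,n_genes Feature counts (defaults 800 and 5000).
#' @param baseline_mean_log_range Natural-log range for baseline means
#'   (default `log(c(20, 3000))`).
#' @param dispersion NB dispersion phi (default 0.2).
#' @param libsize_log_sd SD of log library-size multipliers (default 0.3).
#' @param n_de_mirnas Named counts of planted tumor-vs-normal DE miRNAs per
#'   stratum (`EA.obese`, `EA.lean`, `AA.obese`, `AA.lean`).
#' @param mirna_effect Planted |log2 fold change| for stratum miRNAs
#'   (default 2; must be >= 1 to match the call threshold).
#' @param n_shared_mirnas,shared_effect Planted miRNAs differentially
#'   expressed in tumors of all four strata (shared tumor biology removed by
#'   the signature refinement).
#' @param n_de_genes Named counts of planted obese-vs-lean DE genes per
#'   ancestry.
#' @param gene_effect Planted |log2 fold change| for DE genes (default 2).
#' @param n_true_targets Number of true miRNA-target repression pairs,
#'   split across ancestries proportionally to the obese-stratum planted
#'   miRNA counts (default 30).
#' @param repression_strength Log2 change in a target's mean per 1 SD of its
#'   miRNA's abundance; must be negative (default -1.5).
#' @param decoy_ratio Decoy prediction pairs per true pair (default 3).
#' @param min_planted_mean Minimum baseline mean for planted features
#'   (default 50).
#' @param n_random_genesets,geneset_size Random gene sets accompanying the
#'   planted pathway (defaults 15 sets of 50).
#' @param seed Master seed; every output object draws from its own named
#'   substream derived from it.
#' @return A validated `sim_config` list.
#' @export
sim_config <- function(n_patients_per_cell = 6,
                       n_mirnas = 800,
                       n_genes = 5000,
                       baseline_mean_log_range = log(c(20, 3000)),
                       dispersion = 0.2,
                       libsize_log_sd = 0.3,
                       n_de_mirnas = c(EA.obese = 20, EA.lean = 12,
                                       AA.obese = 16, AA.lean = 12),
                       mirna_effect = 2,
                       n_shared_mirnas = 10,
                       shared_effect = 2,
                       n_de_genes = c(EA = 60, AA = 60),
                       gene_effect = 2,
                       n_true_targets = 30,
                       repression_strength = -1.5,
                       decoy_ratio = 3,
                       min_planted_mean = 50,
                       n_random_genesets = 15,
                       geneset_size = 50,
                       seed = 1) {
  cfg <- list(
    n_patients_per_cell = as.integer(n_patients_per_cell),
    n_mirnas = as.integer(n_mirnas), n_genes = as.integer(n_genes),
    baseline_mean_log_range = baseline_mean_log_range,
    dispersion = dispersion, libsize_log_sd = libsize_log_sd,
    n_de_mirnas = n_de_mirnas, mirna_effect = mirna_effect,
    n_shared_mirnas = as.integer(n_shared_mirnas),
    shared_effect = shared_effect,
    n_de_genes = n_de_genes, gene_effect = gene_effect,
    n_true_targets = as.integer(n_true_targets),
    repression_strength = repression_strength,
    decoy_ratio = decoy_ratio,
    min_planted_mean = min_planted_mean,
    n_random_genesets = as.integer(n_random_genesets),
    geneset_size = as.integer(geneset_size),
    seed = as.integer(seed)
  )
  validate_sim_config(cfg)
  structure(cfg, class = "sim_config")
}

validate_sim_config <- function(cfg) {
  check_scalar_number(cfg$n_patients_per_cell, "n_patients_per_cell", lower = 2)
  check_scalar_number(cfg$n_mirnas, "n_mirnas", lower = 10)
  check_scalar_number(cfg$n_genes, "n_genes", lower = 10)
  check_scalar_number(cfg$dispersion, "dispersion", lower = 1e-8)
  check_scalar_number(cfg$libsize_log_sd, "libsize_log_sd", lower = 0)
  check_scalar_number(cfg$decoy_ratio, "decoy_ratio", lower = 0)
  if (length(cfg$baseline_mean_log_range) != 2 ||
      diff(cfg$baseline_mean_log_range) < 0) {
    stopf("`baseline_mean_log_range` must be an increasing (low, high) pair",
          class = "stratomir_config_error")
  }
  strata <- c("EA.obese", "EA.lean", "AA.obese", "AA.lean")
  if (!all(strata %in% names(cfg$n_de_mirnas)) ||
      any(cfg$n_de_mirnas < 0)) {
    stopf("`n_de_mirnas` must name nonnegative counts for %s",
          paste(strata, collapse = ", "), class = "stratomir_config_error")
  }
  if (!all(c("EA", "AA") %in% names(cfg$n_de_genes)) ||
      any(cfg$n_de_genes < 0)) {
    stopf("`n_de_genes` must name nonnegative counts for EA and AA",
          class = "stratomir_config_error")
  }
  for (eff in c(cfg$mirna_effect, cfg$shared_effect, cfg$gene_effect)) {
    if (abs(eff) < 1) {
      stopf("planted effect sizes must have |log2FC| >= 1 to match the call threshold",
            class = "stratomir_config_error")
    }
  }
  if (cfg$repression_strength >= 0) {
    stopf("`repression_strength` must be negative (repression)",
          class = "stratomir_config_error")
  }
  total_planted <- sum(cfg$n_de_mirnas) + cfg$n_shared_mirnas
  if (total_planted > cfg$n_mirnas) {
    stopf("planted miRNA sets (%d) exceed n_mirnas (%d)", total_planted,
          cfg$n_mirnas, class = "stratomir_config_error")
  }
  if (cfg$n_true_targets + sum(cfg$n_de_genes) > cfg$n_genes) {
    stopf("n_true_targets + planted DE genes exceed n_genes",
          class = "stratomir_config_error")
  }
  invisible(cfg)
}
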