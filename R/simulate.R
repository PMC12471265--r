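#' Simulate a study-shaped dataset with planted ground truth
#'
#' Generates every input the pipeline consumes - miRNA and mRNA count
#' matrices, the sample table, a target-prediction table (true pairs plus
#' decoys), a gene-set collection with one pathway enriched in repressed
#' targets - together with the planted truth against which recovery is
#' scored. Identical (config, seed) gives byte-identical outputs; each
#' output object draws from its own named RNG substream.
#'
#' @param config A [sim_config()].
#' @return A `sim_study` list: `mirna_counts`, `mrna_counts`, `samples`,
#'   `predictions`, `genesets`, `truth` (list of tibbles: `de_mirnas`,
#'   `de_genes`, `true_pairs`, `libsizes`).
#' @export
simulate_study <- function(config = sim_config()) {
  stopifnot(inherits(config, "sim_config"))
  validate_sim_config(config)
  seeds <- seed_substreams(config$seed, c(
    "mirna_baseline", "mirna_planting", "mirna_libsizes", "mirna_counts",
    "mrna_baseline", "mrna_planting", "mrna_libsizes", "mrna_counts",
    "predictions", "genesets"))

  design <- sim_design(config$n_patients_per_cell)
  mirna_ids <- sprintf("sim-miR-%04d", seq_len(config$n_mirnas))
  gene_ids <- sprintf("GENE%05d", seq_len(config$n_genes))

  # --- miRNA layer -------------------------------------------------------
  mirna_base <- withr::with_seed(seeds["mirna_baseline"], {
    exp(stats::runif(config$n_mirnas, config$baseline_mean_log_range[1],
                     config$baseline_mean_log_range[2]))
  })
  names(mirna_base) <- mirna_ids

  planting <- withr::with_seed(seeds["mirna_planting"], {
    plant_mirna_effects(config, mirna_ids, mirna_base)
  })

  mi_samples <- design$mirna
  mi_lib <- withr::with_seed(seeds["mirna_libsizes"], {
    stats::setNames(stats::rlnorm(nrow(mi_samples), 0, config$libsize_log_sd),
                    mi_samples$sample_id)
  })
  mi_mu <- outer(mirna_base, mi_lib)
  for (j in seq_len(nrow(planting))) {
    row <- planting[j, ]
    cols <- mirna_stratum_tumor_samples(mi_samples, row$stratum)
    mi_mu[row$mirna_id, cols] <- mi_mu[row$mirna_id, cols] * 2^row$log2_effect
  }
  mirna_counts <- withr::with_seed(seeds["mirna_counts"], {
    draw_nb(mi_mu, config$dispersion)
  })

  # --- mRNA layer --------------------------------------------------------
  mrna_base <- withr::with_seed(seeds["mrna_baseline"], {
    exp(stats::runif(config$n_genes, config$baseline_mean_log_range[1],
                     config$baseline_mean_log_range[2]))
  })
  names(mrna_base) <- gene_ids

  gene_plan <- withr::with_seed(seeds["mrna_planting"], {
    plant_gene_effects_and_targets(config, gene_ids, mrna_base, planting)
  })

  mr_samples <- design$mrna
  mr_lib <- withr::with_seed(seeds["mrna_libsizes"], {
    stats::setNames(stats::rlnorm(nrow(mr_samples), 0, config$libsize_log_sd),
                    mr_samples$sample_id)
  })
  mr_mu <- outer(mrna_base, mr_lib)
  # independent planted obese-vs-lean effects (obese tumors of the ancestry)
  for (j in seq_len(nrow(gene_plan$de_genes))) {
    row <- gene_plan$de_genes[j, ]
    cols <- mr_samples$sample_id[mr_samples$ancestry == row$ancestry &
                                   mr_samples$bmi_class == "obese"]
    mr_mu[row$gene_id, cols] <- mr_mu[row$gene_id, cols] * 2^row$log2_effect
  }
  # coupling: target mean modulated by the paired miRNA's standardized
  # abundance within the ancestry's tumor samples
  zmat <- mirna_tumor_zscores(mirna_counts, mi_samples)
  for (j in seq_len(nrow(gene_plan$true_pairs))) {
    row <- gene_plan$true_pairs[j, ]
    anc_mr <- mr_samples[mr_samples$ancestry == row$ancestry, ]
    mi_match <- mi_samples[mi_samples$tissue == "tumor" &
                             mi_samples$ancestry == row$ancestry, ]
    mi_of_patient <- stats::setNames(mi_match$sample_id, mi_match$patient_id)
    z <- zmat[row$mirna_id, mi_of_patient[anc_mr$patient_id]]
    mr_mu[row$gene_id, anc_mr$sample_id] <-
      mr_mu[row$gene_id, anc_mr$sample_id] *
      2^(config$repression_strength * z)
  }
  mrna_counts <- withr::with_seed(seeds["mrna_counts"], {
    draw_nb(mr_mu, config$dispersion)
  })

  # --- prediction table and gene sets ------------------------------------
  predictions <- withr::with_seed(seeds["predictions"], {
    build_predictions(config, gene_plan, planting, mirna_ids, gene_ids)
  })
  genesets <- withr::with_seed(seeds["genesets"], {
    build_genesets(config, gene_plan, gene_ids)
  })

  truth <- list(
    de_mirnas = planting,
    de_genes = gene_plan$de_genes,
    true_pairs = gene_plan$true_pairs,
    libsizes = dplyr::bind_rows(
      tibble::tibble(sample_id = names(mi_lib), assay = "miRNA",
                     multiplier = unname(mi_lib)),
      tibble::tibble(sample_id = names(mr_lib), assay = "mRNA",
                     multiplier = unname(mr_lib))
    )
  )
  structure(list(
    mirna_counts = mirna_counts, mrna_counts = mrna_counts,
    samples = dplyr::bind_rows(mi_samples[, 1:6], mr_samples[, 1:6]),
    predictions = predictions, genesets = genesets, truth = truth,
    config = config
  ), class = "sim_study")
}

# Study design tables: paired miRNA tumor/normal libraries for every
# patient, tumor-only mRNA libraries.
sim_design <- function(n_per_cell) {
  cells <- expand.grid(ancestry = ANCESTRY_LEVELS, bmi_class = BMI_LEVELS,
                       idx = seq_len(n_per_cell), stringsAsFactors = FALSE)
  cells$patient_id <- sprintf("%s_%s_%02d", cells$ancestry,
                              substr(cells$bmi_class, 1, 2), cells$idx)
  mirna <- dplyr::bind_rows(lapply(TISSUE_LEVELS, function(tt) {
    tibble::tibble(
      sample_id = sprintf("%s_%s", cells$patient_id,
                          ifelse(tt == "tumor", "T", "N")),
      patient_id = cells$patient_id, ancestry = cells$ancestry,
      bmi_class = cells$bmi_class, tissue = tt, assay = "miRNA")
  }))
  mirna <- mirna[order(mirna$sample_id), ]
  mrna <- tibble::tibble(
    sample_id = sprintf("%s_T_rna", cells$patient_id),
    patient_id = cells$patient_id, ancestry = cells$ancestry,
    bmi_class = cells$bmi_class, tissue = "tumor", assay = "mRNA")
  mrna <- mrna[order(mrna$sample_id), ]
  list(mirna = mirna, mrna = mrna)
}

# Disjoint planted miRNA sets per stratum plus the shared-core block.
# Planted features are drawn among those with baseline mean >=
# min_planted_mean so the recovery conditions are well defined.
plant_mirna_effects <- function(config, mirna_ids, mirna_base) {
  eligible <- mirna_ids[mirna_base >= config$min_planted_mean]
  need <- sum(config$n_de_mirnas) + config$n_shared_mirnas
  if (length(eligible) < need) {
    stopf("only %d features have baseline mean >= %s; %d planted features requested",
          length(eligible), format(config$min_planted_mean), need,
          class = "stratomir_config_error")
  }
  chosen <- sample(eligible, need)
  strata <- c("EA.obese", "EA.lean", "AA.obese", "AA.lean")
  out <- list(tibble::tibble(mirna_id = character(), stratum = character(),
                             log2_effect = numeric()))
  offset <- 0
  for (st in strata) {
    k <- config$n_de_mirnas[[st]]
    if (k > 0) {
      ids <- chosen[offset + seq_len(k)]
      out[[st]] <- tibble::tibble(
        mirna_id = ids, stratum = st,
        log2_effect = sample(c(-1, 1), k, replace = TRUE) * config$mirna_effect)
      offset <- offset + k
    }
  }
  if (config$n_shared_mirnas > 0) {
    ids <- chosen[offset + seq_len(config$n_shared_mirnas)]
    out[["shared"]] <- tibble::tibble(
      mirna_id = ids, stratum = "shared",
      log2_effect = sample(c(-1, 1), config$n_shared_mirnas,
                           replace = TRUE) * config$shared_effect)
  }
  dplyr::bind_rows(out)
}

mirna_stratum_tumor_samples <- function(mi_samples, stratum) {
  tum <- mi_samples[mi_samples$tissue == "tumor", ]
  if (stratum == "shared") return(tum$sample_id)
  parts <- strsplit(stratum, ".", fixed = TRUE)[[1]]
  tum$sample_id[tum$ancestry == parts[1] & tum$bmi_class == parts[2]]
}

# Standardized log2-CPM abundance of every miRNA across each ancestry's
# tumor samples (z within ancestry), used to couple targets to miRNAs.
mirna_tumor_zscores <- function(mirna_counts, mi_samples) {
  tum <- mi_samples[mi_samples$tissue == "tumor", ]
  cpm <- sweep(mirna_counts, 2, colSums(mirna_counts), "/") * 1e6
  lg <- log2(cpm + 1)
  z <- matrix(0, nrow(lg), nrow(tum),
              dimnames = list(rownames(lg), tum$sample_id))
  for (anc in ANCESTRY_LEVELS) {
    cols <- tum$sample_id[tum$ancestry == anc]
    sub <- lg[, cols, drop = FALSE]
    mu <- rowMeans(sub)
    s <- apply(sub, 1, stats::sd)
    s[s == 0] <- 1
    z[, cols] <- (sub - mu) / s
  }
  z
}

# Independent planted DE genes per ancestry plus true target pairs: target
# genes are fresh (their obese-vs-lean signal comes from the coupling),
# miRNAs are up-regulated members of the ancestry's obese-only planted set.
plant_gene_effects_and_targets <- function(config, gene_ids, mrna_base,
                                           planting) {
  eligible <- gene_ids[mrna_base >= config$min_planted_mean]
  n_de <- config$n_de_genes
  n_t <- config$n_true_targets
  need <- sum(n_de) + n_t
  if (length(eligible) < need) {
    stopf("only %d genes have baseline mean >= %s; %d planted genes requested",
          length(eligible), format(config$min_planted_mean), need,
          class = "stratomir_config_error")
  }
  chosen <- sample(eligible, need)
  de_genes <- dplyr::bind_rows(lapply(c("EA", "AA"), function(anc) {
    k <- n_de[[anc]]
    ids <- chosen[(if (anc == "EA") 0 else n_de[["EA"]]) + seq_len(k)]
    tibble::tibble(gene_id = ids, ancestry = anc,
                   log2_effect = sample(c(-1, 1), k, replace = TRUE) *
                     config$gene_effect)
  }))
  target_genes <- chosen[sum(n_de) + seq_len(n_t)]

  n_obese <- c(EA = config$n_de_mirnas[["EA.obese"]],
               AA = config$n_de_mirnas[["AA.obese"]])
  if (n_t > 0 && sum(n_obese) == 0) {
    stopf("n_true_targets > 0 requires planted obese-stratum miRNAs to couple to",
          class = "stratomir_config_error")
  }
  split <- if (n_t == 0) c(EA = 0, AA = 0) else {
    n_ea <- round(n_t * n_obese[["EA"]] / sum(n_obese))
    c(EA = n_ea, AA = n_t - n_ea)
  }
  empty_pairs <- tibble::tibble(mirna_id = character(), gene_id = character(),
                                ancestry = character(), repression = numeric())
  pairs <- list(empty_pairs)
  gi <- 0
  for (anc in c("EA", "AA")) {
    k <- split[[anc]]
    if (k == 0) next
    up <- planting$mirna_id[planting$stratum == paste0(anc, ".obese") &
                              planting$log2_effect > 0]
    if (length(up) == 0) {
      stopf("no up-regulated obese-stratum miRNAs available in %s for target coupling",
            anc, class = "stratomir_config_error")
    }
    pairs[[anc]] <- tibble::tibble(
      mirna_id = sample(up, k, replace = TRUE),
      gene_id = target_genes[gi + seq_len(k)],
      ancestry = anc,
      repression = config$repression_strength)
    gi <- gi + k
  }
  list(de_genes = de_genes, true_pairs = dplyr::bind_rows(pairs))
}

# Prediction table = true pairs plus decoys. Decoys emulate target-
# prediction false positives: pairs whose gene the miRNA does not regulate.
# Half point from planted obese miRNAs at random background genes (tested
# by the network stage whenever the gene is called DE by chance); half are
# random background pairs. Independently planted DE genes are excluded from
# decoy genes because they genuinely co-vary with obesity and would not be
# null partners for an obesity-tracking miRNA.
build_predictions <- function(config, gene_plan, planting, mirna_ids,
                              gene_ids) {
  true_pairs <- gene_plan$true_pairs[, c("mirna_id", "gene_id")]
  n_decoy <- round(config$decoy_ratio * nrow(true_pairs))
  obese_mirnas <- planting$mirna_id[planting$stratum %in%
                                      c("EA.obese", "AA.obese")]
  background_genes <- setdiff(gene_ids, c(gene_plan$de_genes$gene_id,
                                          true_pairs$gene_id))
  mk <- function(n, mpool, gpool) {
    if (n <= 0 || length(mpool) == 0 || length(gpool) == 0) {
      return(tibble::tibble(mirna_id = character(), gene_id = character()))
    }
    tibble::tibble(mirna_id = sample(mpool, n, replace = TRUE),
                   gene_id = sample(gpool, n, replace = TRUE))
  }
  decoys <- dplyr::bind_rows(
    mk(ceiling(n_decoy / 2), obese_mirnas, background_genes),
    mk(floor(n_decoy / 2), mirna_ids, background_genes)
  )
  out <- dplyr::distinct(dplyr::bind_rows(true_pairs, decoys))
  # resampling collisions with true pairs are fine: distinct() keeps one copy
  validate_target_pairs(out)
}

# One pathway enriched in repressed targets (targets plus random padding),
# the rest random sets of the configured size.
build_genesets <- function(config, gene_plan, gene_ids) {
  targets <- unique(gene_plan$true_pairs$gene_id)
  pad <- sample(setdiff(gene_ids, targets),
                max(config$geneset_size - length(targets), 5))
  sets <- list(tibble::tibble(
    set_name = "planted_target_pathway",
    description = "pathway enriched in repressed target genes",
    genes = list(c(targets, pad))))
  for (i in seq_len(config$n_random_genesets)) {
    sets[[i + 1]] <- tibble::tibble(
      set_name = sprintf("random_set_%02d", i),
      description = "random background set",
      genes = list(sample(gene_ids, config$geneset_size)))
  }
  dplyr::bind_rows(sets)
}

draw_nb <- function(mu, phi) {
  counts <- matrix(
    stats::rnbinom(length(mu), size = 1 / phi, mu = as.vector(mu)),
    nrow = nrow(mu), dimnames = dimnames(mu))
  storage.mode(counts) <- "integer"
  counts
}

#' @export
print.sim_study <- function(x, ...) {
  cat(sprintf(paste0(
    "synthetic study: %d miRNAs x %d samples (paired), ",
    "%d genes x %d tumor samples\n",
    "planted: %d stratum miRNAs, %d shared-core miRNAs, %d DE genes, %d true target pairs\n"),
    nrow(x$mirna_counts), ncol(x$mirna_counts),
    nrow(x$mrna_counts), ncol(x$mrna_counts),
    sum(x$truth$de_mirnas$stratum != "shared"),
    sum(x$truth$de_mirnas$stratum == "shared"),
    nrow(x$truth$de_genes), nrow(x$truth$true_pairs)))
  invisible(x)
}
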