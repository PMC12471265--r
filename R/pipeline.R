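#' Configuration for an end-to-end study run
#'
#' Bundles every stage parameter of the pipeline: the synthetic-study
#' generator configuration (or a pre-built dataset), the low-count filter,
#' the per-assay differential-expression thresholds, the correlation
#' significance level, and the enrichment universe mode.
#'
#' @param sim A [sim_config()] describing the dataset to generate.
#' @param min_count,min_fraction Low-count filter parameters.
#' @param mirna_thresholds,mrna_thresholds Threshold overrides passed to
#'   [run_study_contrasts()].
#' @param alpha Correlation significance threshold (inclusive).
#' @param exact_n Exact-permutation cutoff for [spearman_test()].
#' @param universe_mode Enrichment background
#'   (`"all_measured_genes"` or `"geneset_union"`).
#' @return A `study_config` list.
#' @export
study_config <- function(sim = sim_config(), min_count = 5,
                         min_fraction = 0.8,
                         mirna_thresholds = list(), mrna_thresholds = list(),
                         alpha = 0.05, exact_n = 10,
                         universe_mode = "all_measured_genes") {
  structure(list(
    sim = sim, min_count = min_count, min_fraction = min_fraction,
    mirna_thresholds = mirna_thresholds, mrna_thresholds = mrna_thresholds,
    alpha = alpha, exact_n = exact_n, universe_mode = universe_mode
  ), class = "study_config")
}

#' Validate a study configuration
#'
#' Checks every field against its domain and returns all violations rather
#' than stopping at the first.
#'
#' @param config A [study_config()] (or plain list).
#' @return A tibble with columns `field`, `problem`; zero rows when valid.
#' @export
validate_study_config <- function(config) {
  v <- list()
  note <- function(field, problem) {
    v[[length(v) + 1]] <<- tibble::tibble(field = field, problem = problem)
  }
  required <- c("sim", "min_count", "min_fraction", "mirna_thresholds",
                "mrna_thresholds", "alpha", "exact_n", "universe_mode")
  for (f in setdiff(required, names(config))) {
    note(f, "required field missing")
  }
  chk_num <- function(field, lower, upper) {
    x <- config[[field]]
    if (is.null(x)) return()
    if (!is.numeric(x) || length(x) != 1 || !is.finite(x) ||
        x < lower || x > upper) {
      note(field, sprintf("must be a single number in [%s, %s]",
                          format(lower), format(upper)))
    }
  }
  chk_num("min_count", 0, Inf)
  chk_num("min_fraction", 1e-12, 1)
  chk_num("alpha", 0, 1)
  chk_num("exact_n", 4, 1000)
  if (!is.null(config$universe_mode) &&
      !identical(config$universe_mode, "all_measured_genes") &&
      !identical(config$universe_mode, "geneset_union")) {
    note("universe_mode",
         "must be 'all_measured_genes' or 'geneset_union'")
  }
  if (!is.null(config$sim)) {
    ok <- tryCatch({validate_sim_config(config$sim); TRUE},
                   error = function(e) {
                     note("sim", conditionMessage(e))
                     FALSE
                   })
  }
  if (length(v) == 0) {
    return(tibble::tibble(field = character(), problem = character()))
  }
  dplyr::bind_rows(v)
}

#' Run the full analysis pipeline
#'
#' Executes simulate -> filter/normalize -> differential expression ->
#' signature subtraction -> prediction-restricted correlation network ->
#' regulation classification -> enrichment -> two-cluster separation check,
#' and returns a structured run report. Deterministic given
#' (config, generator seed). In addition to the study's eight contrasts, a
#' miRNA obese-vs-lean contrast per ancestry is fitted on tumor samples to
#' supply the miRNA fold changes that the regulation-classification rule
#' reads.
#'
#' @param config A [study_config()].
#' @param data Optional pre-built `sim_study` (or equivalently shaped list);
#'   when NULL the generator runs with `config$sim`.
#' @return A `study_report` object.
#' @export
run_study <- function(config = study_config(), data = NULL) {
  violations <- validate_study_config(config)
  if (nrow(violations) > 0) {
    stopf("invalid study configuration:\n%s",
          paste(sprintf("- %s: %s", violations$field, violations$problem),
                collapse = "\n"),
          class = "stratomir_config_error")
  }
  timings <- list()
  clock <- function(stage, expr) {
    t0 <- Sys.time()
    out <- force(expr)
    timings[[stage]] <<- as.numeric(difftime(Sys.time(), t0, units = "secs"))
    out
  }

  data <- clock("simulate", if (is.null(data)) simulate_study(config$sim) else data)

  contrasts <- clock("diffexp", run_study_contrasts(
    data$mirna_counts, data$mrna_counts, data$samples,
    mirna_thresholds = config$mirna_thresholds,
    mrna_thresholds = config$mrna_thresholds,
    min_count = config$min_count, min_fraction = config$min_fraction))

  needed <- c("mirna_EA_obese_tvn", "mirna_EA_lean_tvn", "mirna_AA_obese_tvn",
              "mirna_AA_lean_tvn", "mirna_EA_both_tvn", "mirna_AA_both_tvn")
  missing <- setdiff(needed, names(contrasts))
  if (length(missing) > 0) {
    stopf("contrast stage did not produce: %s", paste(missing, collapse = ", "))
  }
  signature <- clock("signature", run_signature_pipeline(list(
    ea_obese = contrasts$mirna_EA_obese_tvn,
    ea_lean = contrasts$mirna_EA_lean_tvn,
    aa_obese = contrasts$mirna_AA_obese_tvn,
    aa_lean = contrasts$mirna_AA_lean_tvn,
    ea_all = contrasts$mirna_EA_both_tvn,
    aa_all = contrasts$mirna_AA_both_tvn)))

  mirna_filtered <- attr(contrasts, "mirna_filtered")
  mrna_filtered <- attr(contrasts, "mrna_filtered")
  mirna_factors <- attr(contrasts, "mirna_factors")
  mrna_factors <- attr(contrasts, "mrna_factors")
  mirna_expr <- log2_normalize(mirna_filtered, mirna_factors)
  mrna_expr <- log2_normalize(mrna_filtered, mrna_factors)

  # miRNA obese-vs-lean fold changes (tumors only) for edge classification
  mirna_ovl <- clock("mirna_ovl", {
    out <- list()
    for (anc in ANCESTRY_LEVELS) {
      design <- de_design("miRNA", "obese_vs_lean", ancestry = anc,
                          pairing = "unpaired")
      out[[anc]] <- nb_wald_test(mirna_filtered, data$samples, design,
                                 mirna_factors)
    }
    out
  })

  net <- clock("network", {
    out <- list()
    for (anc in ANCESTRY_LEVELS) {
      refined <- signature$sets[[if (anc == "EA") "ea_refined" else "aa_refined"]]
      gene_de_tab <- contrasts[[sprintf("mrna_%s_ovl", anc)]]
      if (is.null(gene_de_tab)) next
      edges <- correlate_pairs(
        mirna_expr, mrna_expr, data$predictions,
        de_mirnas = refined, de_genes = de_features(gene_de_tab),
        samples = data$samples, ancestry = anc,
        alpha = config$alpha, exact_n = config$exact_n)
      out[[anc]] <- classify_edges(edges, mirna_ovl[[anc]], gene_de_tab)
    }
    out
  })
  summaries <- lapply(net, network_summary)

  enrichment <- clock("enrichment", {
    lapply(net, function(edges) {
      suppressWarnings(enrich_network_targets(
        edges, data$genesets, universe = rownames(mrna_filtered),
        universe_mode = config$universe_mode, alpha = config$alpha))
    })
  })

  separation <- clock("separation", {
    out <- list()
    zs <- suppressWarnings(zscore_rows(mirna_expr))
    for (anc in ANCESTRY_LEVELS) {
      refined <- signature$sets[[if (anc == "EA") "ea_refined" else "aa_refined"]]
      feats <- intersect(refined, rownames(zs))
      s <- data$samples[data$samples$assay == "miRNA" &
                          data$samples$ancestry == anc &
                          data$samples$bmi_class == "obese", ]
      if (length(feats) < 2 || nrow(s) < 4) {
        warnf("separation check skipped for %s (too few features or samples)", anc)
        next
      }
      out[[anc]] <- two_cluster_purity(
        zs[feats, s$sample_id, drop = FALSE],
        stats::setNames(s$tissue, s$sample_id))
    }
    out
  })

  structure(list(
    config = config, data = data, contrasts = contrasts,
    mirna_ovl = mirna_ovl, signature = signature, edges = net,
    network_summaries = summaries, enrichment = enrichment,
    separation = separation,
    timings = tibble::tibble(stage = names(timings),
                             seconds = unlist(timings, use.names = FALSE))
  ), class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("stratomir study report\n")
  print(glance(x))
  invisible(x)
}

#' @export
glance.study_report <- function(x, ...) {
  tibble::tibble(
    n_mirna_contrasts = sum(grepl("^mirna_", names(x$contrasts))),
    n_mrna_contrasts = sum(grepl("^mrna_", names(x$contrasts))),
    ea_refined = length(x$signature$sets$ea_refined),
    aa_refined = length(x$signature$sets$aa_refined),
    ea_edges = if (is.null(x$edges$EA)) NA_integer_ else nrow(x$edges$EA),
    aa_edges = if (is.null(x$edges$AA)) NA_integer_ else nrow(x$edges$AA),
    ea_purity = if (is.null(x$separation$EA)) NA_real_ else x$separation$EA$purity,
    aa_purity = if (is.null(x$separation$AA)) NA_real_ else x$separation$AA$purity
  )
}

#' @export
tidy.study_report <- function(x, ...) {
  card <- x$signature$cardinality
  extra <- dplyr::bind_rows(lapply(names(x$network_summaries), function(anc) {
    s <- x$network_summaries[[anc]]
    tibble::tibble(
      set = sprintf(c("%s_edges", "%s_inverse_edges", "%s_network_mirnas",
                      "%s_network_genes"), tolower(anc)),
      size = c(s$n_edges, s$n_inverse, s$n_mirnas, s$n_genes),
      parents = sprintf("%s network", anc))
  }))
  dplyr::bind_rows(card, extra)
}

#' Write the artifacts of a study run to a directory
#'
#' Serializes the run's tables in the package's external formats: DE tables
#' and normalization factors as TSV, signatures and provenance as TSV, edge
#' lists as TSV and SIF, enrichment tables as TSV, plus a flat key-value
#' report (`report.tsv`) of every cardinality in [tidy.study_report()].
#'
#' @param report A `study_report`.
#' @param outdir Output directory (created if needed).
#' @return `outdir`, invisibly.
#' @export
write_study_report <- function(report, outdir) {
  dir.create(outdir, showWarnings = FALSE, recursive = TRUE)
  for (nm in names(report$contrasts)) {
    readr::write_tsv(report$contrasts[[nm]],
                     file.path(outdir, sprintf("de_%s.tsv", nm)),
                     progress = FALSE)
  }
  sig <- report$signature
  readr::write_tsv(sig$cardinality, file.path(outdir, "signature_sets.tsv"),
                   progress = FALSE)
  readr::write_tsv(sig$provenance, file.path(outdir, "signature_provenance.tsv"),
                   progress = FALSE)
  for (anc in names(report$edges)) {
    write_edges(report$edges[[anc]],
                file.path(outdir, sprintf("edges_%s.tsv", tolower(anc))), "tsv")
    write_edges(report$edges[[anc]],
                file.path(outdir, sprintf("network_%s.sif", tolower(anc))), "sif")
  }
  for (anc in names(report$enrichment)) {
    enr <- report$enrichment[[anc]]
    enr$hit_ids <- vapply(enr$hit_ids, paste, character(1), collapse = ",")
    readr::write_tsv(enr,
                     file.path(outdir, sprintf("enrichment_%s.tsv", tolower(anc))),
                     progress = FALSE)
  }
  readr::write_tsv(tidy(report), file.path(outdir, "report.tsv"),
                   progress = FALSE)
  invisible(outdir)
}
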