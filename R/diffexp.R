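#' Benjamini-Hochberg false discovery rates
#'
#' Step-up BH adjustment with monotonicity enforcement, order-preserving with
#' the input. Thin wrapper over [stats::p.adjust()]; missing p-values are
#' propagated as missing with a warning.
#'
#' @param p Numeric vector of p-values in \[0, 1\] (NA/NaN allowed).
#' @return Adjusted q-values, same length and order as `p`.
#' @export
bh_fdr <- function(p) {
  if (!is.numeric(p)) stopf("`p` must be numeric")
  bad <- is.na(p)
  if (any(bad)) warnf("%d missing p-value(s) propagated as NA", sum(bad))
  if (any(p[!bad] < 0 | p[!bad] > 1)) {
    stopf("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p, method = "BH", n = sum(!bad))
}

#' Estimate per-feature negative-binomial dispersions
#'
#' Method-of-moments estimate on offset-normalized counts,
#' `phi_hat = max(phi_min, (s^2 - mu) / mu^2)` under the parameterization
#' `variance = mu + phi * mu^2`, shrunk toward a mean-dispersion trend line
#' (log-log linear fit) by geometric 50/50 blending. Features with zero mean
#' across all samples are excluded with a warning (they should have been
#' removed by the count filter).
#'
#' @param counts Count matrix for the samples being modeled.
#' @param effective_sizes Named (by sample id) or column-aligned vector of
#'   effective library sizes.
#' @param phi_min Dispersion floor (default 1e-4).
#' @param shrink Weight on the trend line in the log-scale blend
#'   (default 0.5).
#' @return A tibble with columns `feature_id`, `mean`, `phi_mom`,
#'   `phi_trend`, `phi`.
#' @export
estimate_dispersions <- function(counts, effective_sizes, phi_min = 1e-4,
                                 shrink = 0.5) {
  counts <- validate_count_matrix(counts)
  if (!is.null(names(effective_sizes))) {
    effective_sizes <- effective_sizes[colnames(counts)]
  }
  if (length(effective_sizes) != ncol(counts) || any(!is.finite(effective_sizes)) ||
      any(effective_sizes <= 0)) {
    stopf("`effective_sizes` must be positive and cover every sample")
  }
  check_scalar_number(phi_min, "phi_min", lower = 0)
  sf <- effective_sizes / geometric_mean(effective_sizes)
  norm <- sweep(counts, 2, sf, "/")
  mu <- rowMeans(norm)
  zero <- mu == 0
  if (any(zero)) {
    warnf("%d feature(s) with zero mean excluded from dispersion estimation",
          sum(zero))
    norm <- norm[!zero, , drop = FALSE]
    mu <- mu[!zero]
  }
  s2 <- apply(norm, 1, stats::var)
  phi_mom <- pmax(phi_min, (s2 - mu) / mu^2)

  informative <- phi_mom > phi_min
  if (sum(informative) >= 10) {
    fit <- stats::lm(log(phi_mom[informative]) ~ log(mu[informative]))
    phi_trend <- exp(fit$coefficients[1] + fit$coefficients[2] * log(mu))
  } else {
    phi_trend <- rep(max(stats::median(phi_mom), phi_min), length(mu))
  }
  phi_trend <- pmin(pmax(phi_trend, phi_min), 100)
  phi <- pmax(phi_min, exp((1 - shrink) * log(phi_mom) + shrink * log(phi_trend)))
  tibble::tibble(
    feature_id = rownames(norm),
    mean = unname(mu),
    phi_mom = unname(phi_mom),
    phi_trend = unname(phi_trend),
    phi = unname(phi)
  )
}

#' Describe a differential-expression contrast
#'
#' Bundles the stratum filter, contrast, pairing and call thresholds for one
#' comparison. Tumor-vs-normal contrasts report tumor over normal;
#' obese-vs-lean contrasts run on tumor samples only and report obese over
#' lean. Exactly one thresholding rule governs the `is_de` call: either
#' FDR + minimum absolute log2 fold change (`use_raw_p = FALSE`) or a raw
#' p-value cutoff (`use_raw_p = TRUE`).
#'
#' @param assay `"miRNA"` or `"mRNA"`.
#' @param contrast `"tumor_vs_normal"` or `"obese_vs_lean"`.
#' @param ancestry `"EA"`, `"AA"` or `"both"`.
#' @param bmi_class `"obese"`, `"lean"` or `"both"` (tumor-vs-normal only).
#' @param pairing `"paired_by_patient"` or `"unpaired"`.
#' @param fdr_max,min_abs_log2fc Thresholds for the FDR + fold-change rule.
#' @param use_raw_p Use the raw p-value rule instead.
#' @param p_max Threshold for the raw p-value rule.
#' @return A `de_design` list.
#' @export
de_design <- function(assay, contrast = c("tumor_vs_normal", "obese_vs_lean"),
                      ancestry = "both", bmi_class = "both",
                      pairing = c("unpaired", "paired_by_patient"),
                      fdr_max = 0.05, min_abs_log2fc = 1,
                      use_raw_p = FALSE, p_max = 0.05) {
  contrast <- match.arg(contrast)
  pairing <- match.arg(pairing)
  check_enum(assay, ASSAY_LEVELS, "assay")
  check_enum(ancestry, c(ANCESTRY_LEVELS, "both"), "ancestry")
  check_enum(bmi_class, c(BMI_LEVELS, "both"), "bmi_class")
  if (contrast == "obese_vs_lean" && bmi_class != "both") {
    stopf("obese_vs_lean contrasts use both BMI classes by definition")
  }
  structure(list(
    assay = assay, contrast = contrast, ancestry = ancestry,
    bmi_class = bmi_class, pairing = pairing,
    thresholds = list(fdr_max = fdr_max, min_abs_log2fc = min_abs_log2fc,
                      use_raw_p = isTRUE(use_raw_p), p_max = p_max)
  ), class = "de_design")
}

#' @export
format.de_design <- function(x, ...) {
  sprintf("%s %s [ancestry %s, bmi %s, %s]", x$assay, x$contrast,
          x$ancestry, x$bmi_class, x$pairing)
}

#' @export
print.de_design <- function(x, ...) {
  cat(format(x), "\n")
  invisible(x)
}

# Select the samples a design applies to and define the contrast factor
# (reference level first).
design_samples <- function(samples, design) {
  s <- samples[samples$assay == design$assay, , drop = FALSE]
  if (design$ancestry != "both") s <- s[s$ancestry == design$ancestry, , drop = FALSE]
  if (design$contrast == "tumor_vs_normal") {
    if (design$bmi_class != "both") s <- s[s$bmi_class == design$bmi_class, , drop = FALSE]
    s$grp <- factor(s$tissue, levels = c("normal", "tumor"))
  } else {
    s <- s[s$tissue == "tumor", , drop = FALSE]
    s$grp <- factor(s$bmi_class, levels = c("lean", "obese"))
  }
  s
}

#' Negative-binomial Wald differential expression for one contrast
#'
#' Per feature, fits an NB log-linear model with a log effective-library-size
#' offset (group term plus fixed patient effects when paired), with
#' dispersions from [estimate_dispersions()], and reports the contrast
#' coefficient as a log2 fold change with a two-sided Wald p-value and BH
#' FDR across tested features. Features whose fit fails or does not converge
#' are reported with `p = 1`, `fdr = 1` and flag `"unstable"` rather than
#' crashing the run.
#'
#' @param counts Count matrix (already low-count filtered).
#' @param samples Sample table covering the counts' samples.
#' @param design A [de_design()].
#' @param factors Normalization factors from [tmm_factors()] covering the
#'   design's samples.
#' @return A `de_table` tibble with columns `feature_id`, `base_mean`,
#'   `log2_fc`, `p`, `fdr`, `is_de`, `n_level1`, `n_level2`, `flag`, and
#'   attributes `design` and `comparison`.
#' @export
nb_wald_test <- function(counts, samples, design, factors) {
  counts <- validate_count_matrix(counts)
  samples <- validate_sample_table(samples, allow_unpaired = TRUE)
  stopifnot(inherits(design, "de_design"))
  s <- design_samples(samples, design)
  s <- s[s$sample_id %in% colnames(counts), , drop = FALSE]
  if (design$pairing == "paired_by_patient") {
    with_both <- names(which(tapply(as.integer(s$grp), s$patient_id,
                                    function(g) length(unique(g)) == 2)))
    dropped <- setdiff(unique(s$patient_id), with_both)
    if (length(dropped) > 0) {
      warnf("dropping %d patient(s) without both contrast levels: %s",
            length(dropped), paste(dropped, collapse = ", "))
    }
    s <- s[s$patient_id %in% with_both, , drop = FALSE]
  }
  lev_n <- table(s$grp)
  if (any(lev_n < 2)) {
    stopf("contrast '%s' needs at least 2 samples per level (have %s)",
          format(design), paste(lev_n, collapse = " vs "))
  }
  y_all <- counts[, s$sample_id, drop = FALSE]
  eff <- factors$effective_size[match(s$sample_id, factors$sample_id)]
  if (anyNA(eff)) stopf("normalization factors missing for design samples")

  disp <- estimate_dispersions(y_all, stats::setNames(eff, s$sample_id))
  y_all <- y_all[disp$feature_id, , drop = FALSE]

  if (design$pairing == "paired_by_patient" &&
      length(unique(s$patient_id)) > 1) {
    X <- stats::model.matrix(~ factor(patient_id) + grp, data = s)
  } else {
    X <- stats::model.matrix(~ grp, data = s)
  }
  offset <- log(eff)
  coef_idx <- ncol(X)

  sf <- eff / geometric_mean(eff)
  base_mean <- rowMeans(sweep(y_all, 2, sf, "/"))

  nfeat <- nrow(y_all)
  log2_fc <- numeric(nfeat)
  pval <- numeric(nfeat)
  flag <- rep("ok", nfeat)
  for (i in seq_len(nfeat)) {
    res <- nb_wald_single(y_all[i, ], X, offset, disp$phi[i], coef_idx)
    log2_fc[i] <- res$log2_fc
    pval[i] <- res$p
    flag[i] <- res$flag
  }
  fdr <- bh_fdr(pval)
  th <- design$thresholds
  is_de <- if (th$use_raw_p) {
    pval <= th$p_max
  } else {
    fdr <= th$fdr_max & abs(log2_fc) >= th$min_abs_log2fc
  }
  out <- tibble::tibble(
    feature_id = rownames(y_all),
    base_mean = unname(base_mean),
    log2_fc = log2_fc,
    p = pval,
    fdr = fdr,
    is_de = is_de & flag == "ok",
    n_level1 = unname(lev_n[1]),
    n_level2 = unname(lev_n[2]),
    flag = flag
  )
  attr(out, "design") <- design
  attr(out, "comparison") <- format(design)
  class(out) <- c("de_table", class(out))
  out
}

# One feature's NB GLM Wald test: glm.fit with a fixed-theta NB family,
# Wald z from the dispersion-1 covariance of the coefficient.
nb_wald_single <- function(y, X, offset, phi, coef_idx) {
  fail <- list(log2_fc = 0, p = 1, flag = "unstable")
  fit <- tryCatch(
    suppressWarnings(stats::glm.fit(
      x = X, y = y, offset = offset,
      family = MASS::negative.binomial(theta = 1 / phi, link = "log")
    )),
    error = function(e) NULL
  )
  if (is.null(fit) || !fit$converged || fit$boundary) return(fail)
  b <- fit$coefficients[coef_idx]
  w <- fit$weights
  xtx <- crossprod(X * sqrt(w))
  cov <- tryCatch(chol2inv(chol(xtx)), error = function(e) NULL)
  if (is.null(cov)) return(fail)
  se <- sqrt(cov[coef_idx, coef_idx])
  if (!is.finite(b) || !is.finite(se) || se <= 0) return(fail)
  z <- b / se
  list(log2_fc = unname(b) / log(2),
       p = 2 * stats::pnorm(-abs(z)),
       flag = "ok")
}
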