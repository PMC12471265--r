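#' Remove low-count features
#'
#' Keeps features with at least `min_count` counts in at least a fraction
#' `min_fraction` of samples. "At least 80% of samples" is interpreted with
#' ceiling: a feature must qualify in at least `ceiling(min_fraction * n)`
#' samples, the conservative reading of the rule. The operation is
#' idempotent and leaves the sample set unchanged.
#'
#' @param counts A count matrix (features x samples).
#' @param min_count Minimum count for a sample to qualify (default 5).
#' @param min_fraction Minimum fraction of qualifying samples (default 0.8).
#' @return The filtered count matrix.
#' @export
filter_low_counts <- function(counts, min_count = 5, min_fraction = 0.8) {
  counts <- validate_count_matrix(counts)
  if (ncol(counts) == 0) stopf("count matrix has zero samples")
  check_scalar_number(min_count, "min_count", lower = 0)
  check_scalar_number(min_fraction, "min_fraction", lower = 1e-12, upper = 1)
  need <- ceiling(min_fraction * ncol(counts))
  keep <- rowSums(counts >= min_count) >= need
  counts[keep, , drop = FALSE]
}

#' Log2 counts-per-million on TMM effective library sizes
#'
#' Computes `log2(count / effective_size * scale + prior)` per cell, where
#' the effective size is the TMM-scaled library size from [tmm_factors()].
#' With the default prior of 1, a zero count maps to exactly 0.
#'
#' @param counts A count matrix.
#' @param factors Normalization factors from [tmm_factors()].
#' @param prior Pseudo-count added inside the log (default 1).
#' @param scale Per-million scaling constant (default 1e6).
#' @return A numeric matrix with attribute `transform = "log2cpm"`.
#' @export
log2_normalize <- function(counts, factors, prior = 1.0, scale = 1e6) {
  counts <- validate_count_matrix(counts)
  missing <- setdiff(colnames(counts), factors$sample_id)
  if (length(missing) > 0) {
    stopf("normalization factors missing for sample(s): %s",
          paste(missing, collapse = ", "))
  }
  eff <- factors$effective_size[match(colnames(counts), factors$sample_id)]
  if (any(eff <= 0)) {
    stopf("effective library size must be positive for all samples")
  }
  out <- log2(sweep(counts, 2, eff, "/") * scale + prior)
  attr(out, "transform") <- "log2cpm"
  out
}

#' Z-score expression rows
#'
#' Centers and scales each feature across samples using the sample (n - 1)
#' standard deviation, the convention used for heatmap displays. Constant
#' rows cannot be scaled; they are emitted as all-zeros with a warning.
#'
#' @param expr A numeric expression matrix (e.g. from [log2_normalize()]).
#' @return A matrix with attribute `transform = "zscore"`; every
#'   non-constant row has mean 0 and sd 1.
#' @export
zscore_rows <- function(expr) {
  if (!is.matrix(expr) || !is.numeric(expr)) stopf("`expr` must be a numeric matrix")
  if (ncol(expr) < 2) stopf("z-scoring requires at least 2 samples")
  mu <- rowMeans(expr)
  s <- apply(expr, 1, stats::sd)
  const <- s == 0 | !is.finite(s)
  if (any(const)) {
    warnf("%d constant row(s) emitted as all-zeros: %s", sum(const),
          paste(head(rownames(expr)[const], 5), collapse = ", "))
    s[const] <- 1
  }
  out <- (expr - mu) / s
  out[const, ] <- 0
  attr(out, "transform") <- "zscore"
  out
}
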