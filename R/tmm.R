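#' Trimmed-mean-of-M-values normalization factors
#'
#' Computes between-sample scaling factors by the published TMM procedure:
#' the reference sample is the one whose upper-quartile relative abundance is
#' closest to the mean upper-quartile; per sample, log2 abundance ratios
#' against the reference (M-values) are trimmed by `trim_m` on M and `trim_a`
#' on average log abundance (A), the surviving M-values are averaged with
#' inverse asymptotic-variance weights, and the resulting factors are
#' re-centered to geometric mean 1. Features with a zero count in either the
#' sample or the reference drop out of that sample's comparison.
#'
#' @param counts A count matrix (features x samples), every sample with a
#'   positive library size.
#' @param trim_m Two-sided trim fraction on M-values (default 0.30, the
#'   method's published default).
#' @param trim_a Two-sided trim fraction on A-values (default 0.05).
#' @return A tibble with columns `sample_id`, `library_size`, `tmm_factor`,
#'   `effective_size` (= library_size * tmm_factor) and attribute
#'   `reference_sample`.
#' @export
tmm_factors <- function(counts, trim_m = 0.30, trim_a = 0.05) {
  counts <- validate_count_matrix(counts)
  check_scalar_number(trim_m, "trim_m", lower = 0, upper = 0.49)
  check_scalar_number(trim_a, "trim_a", lower = 0, upper = 0.49)
  lib <- colSums(counts)
  if (any(lib == 0)) {
    stopf("sample(s) with zero library size: %s",
          paste(colnames(counts)[lib == 0], collapse = ", "))
  }
  # reference: upper-quartile relative abundance closest to the mean
  uq <- apply(counts, 2, stats::quantile, probs = 0.75) / lib
  ref_idx <- which.min(abs(uq - mean(uq)))
  ref <- counts[, ref_idx]
  ref_lib <- lib[ref_idx]

  f <- vapply(seq_len(ncol(counts)), function(j) {
    tmm_pair_factor(counts[, j], lib[j], ref, ref_lib,
                    trim_m = trim_m, trim_a = trim_a,
                    sample_id = colnames(counts)[j])
  }, numeric(1))
  f <- f / geometric_mean(f)
  out <- tibble::tibble(
    sample_id = colnames(counts),
    library_size = unname(lib),
    tmm_factor = unname(f),
    effective_size = unname(lib * f)
  )
  attr(out, "reference_sample") <- colnames(counts)[ref_idx]
  out
}

# One sample's unscaled TMM factor against the reference (log2 ratios of
# library-normalized abundances, double trim, precision weighting).
tmm_pair_factor <- function(x, libx, ref, libr, trim_m, trim_a, sample_id) {
  obs <- x / libx
  rfp <- ref / libr
  M <- log2(obs / rfp)
  A <- 0.5 * log2(obs * rfp)
  # asymptotic variance of M under binomial sampling
  v <- (libx - x) / (libx * x) + (libr - ref) / (libr * ref)
  keep <- is.finite(M) & is.finite(A) & A > -1e10
  if (!any(keep)) {
    stopf("sample '%s' shares no nonzero features with the TMM reference",
          sample_id)
  }
  M <- M[keep]; A <- A[keep]; v <- v[keep]
  if (max(abs(M)) < 1e-6) return(1)
  n <- length(M)
  lo_m <- floor(n * trim_m) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * trim_a) + 1
  hi_a <- n + 1 - lo_a
  rm_ <- rank(M); ra <- rank(A)
  sel <- rm_ >= lo_m & rm_ <= hi_m & ra >= lo_a & ra <= hi_a
  if (!any(sel)) return(1)
  f <- sum(M[sel] / v[sel], na.rm = TRUE) / sum(1 / v[sel], na.rm = TRUE)
  if (!is.finite(f)) return(1)
  2^f
}
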