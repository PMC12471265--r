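# Shared internal helpers: argument checks, enum validation, seed substreams.

stopf <- function(fmt, ..., class = "stratomir_error") {
  rlang::abort(sprintf(fmt, ...), class = class)
}

warnf <- function(fmt, ...) {
  rlang::warn(sprintf(fmt, ...))
}

#' @noRd
check_enum <- function(x, allowed, what, context = "value") {
  bad <- setdiff(unique(as.character(x)), allowed)
  if (length(bad) > 0) {
    stopf("invalid %s %s: %s (allowed: %s)",
          what, context, paste(bad, collapse = ", "),
          paste(allowed, collapse = ", "),
          class = "stratomir_format_error")
  }
  invisible(x)
}

check_scalar_number <- function(x, name, lower = -Inf, upper = Inf) {
  if (!is.numeric(x) || length(x) != 1 || !is.finite(x) || x < lower || x > upper) {
    stopf("`%s` must be a single finite number in [%s, %s]", name,
          format(lower), format(upper))
  }
  invisible(x)
}

# Deterministic named sub-seeds from one master seed: the master seed draws a
# fixed-order table of 32-bit sub-seeds, so each output object gets its own
# RNG substream and appending a new name never perturbs earlier streams.
seed_substreams <- function(seed, names) {
  withr::with_seed(as.integer(seed), {
    subs <- sample.int(.Machine$integer.max - 1L, length(names))
  })
  stats::setNames(as.integer(subs), names)
}

geometric_mean <- function(x) exp(mean(log(x)))

ANCESTRY_LEVELS <- c("EA", "AA")
BMI_LEVELS <- c("obese", "lean")
TISSUE_LEVELS <- c("tumor", "normal")
ASSAY_LEVELS <- c("miRNA", "mRNA")
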