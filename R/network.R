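#' Spearman rank correlation with exact small-sample p-values
#'
#' Computes rho as the Pearson correlation of midranks (average ranks for
#' ties). The two-sided p-value uses exact permutation enumeration of all
#' `n!` rank arrangements for `n < exact_n` (small samples, where the
#' t-approximation is unreliable) and the t-approximation
#' `t = rho * sqrt((n - 2) / (1 - rho^2))` otherwise.
#'
#' @param x,y Numeric vectors of equal length `n >= 4`; neither constant.
#' @param exact_n Use exact enumeration for `n < exact_n` (default 10).
#' @return A list with `rho`, `p`, `n` and `method` ("exact" or "t-approx").
#' @export
spearman_test <- function(x, y, exact_n = 10) {
  n <- length(x)
  if (length(y) != n || n < 4) {
    stopf("`x` and `y` must have equal length >= 4")
  }
  if (anyNA(x) || anyNA(y)) stopf("missing values are not supported")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    stopf("correlation undefined for a constant vector",
          class = "stratomir_constant_error")
  }
  rx <- rank(x)
  ry <- rank(y)
  rho <- stats::cor(rx, ry)
  if (n < exact_n) {
    p <- spearman_exact_p(rx, ry, rho)
    method <- "exact"
  } else {
    if (abs(rho) >= 1) {
      p <- 0
    } else {
      tstat <- rho * sqrt((n - 2) / (1 - rho^2))
      p <- 2 * stats::pt(-abs(tstat), df = n - 2)
    }
    method <- "t-approx"
  }
  list(rho = rho, p = min(1, p), n = n, method = method)
}

# Exact two-sided permutation p: enumerate all n! arrangements of y's ranks
# against x's ranks and count |rho_perm| >= |rho_obs| (within tolerance).
# Conditions on the observed tie patterns because midranks are permuted.
spearman_exact_p <- function(rx, ry, rho_obs) {
  n <- length(rx)
  perms <- all_permutations(n)
  # rho is monotone in sum(rx_perm * ry); compute all inner products at once
  ips <- matrix(rx[perms], nrow = nrow(perms)) %*% ry
  mx <- mean(rx); my <- mean(ry)
  denom <- sqrt(sum((rx - mx)^2) * sum((ry - my)^2))
  rhos <- (ips - n * mx * my) / denom
  mean(abs(rhos) >= abs(rho_obs) - 1e-12)
}

# All permutations of 1..n as a (n! x n) integer matrix, in deterministic
# order. n is small (< 10) by construction.
all_permutations <- function(n) {
  if (n == 1) return(matrix(1L, 1, 1))
  sub <- all_permutations(n - 1L)
  out <- matrix(0L, nrow = n * nrow(sub), ncol = n)
  for (k in seq_len(n)) {
    rows <- (k - 1L) * nrow(sub) + seq_len(nrow(sub))
    out[rows, 1L] <- k
    rest <- seq_len(n)[-k]
    out[rows, -1L] <- matrix(rest[sub], nrow(sub), n - 1L)
  }
  out
}

#' Correlate predicted miRNA-target pairs over tumor samples
#'
#' Tests exactly the (miRNA, gene) pairs with the miRNA in the refined
#' signature, the gene in the mRNA DE list, and the pair present in the
#' target-prediction table, using Spearman correlation across the given
#' ancestry's tumor samples (miRNA and mRNA libraries are matched by
#' patient). Pairs with `p <= alpha` (inclusive) are retained. Pairs with
#' constant expression in either member are skipped and counted.
#'
#' @param mirna_expr,mrna_expr Normalized expression matrices
#'   (e.g. [log2_normalize()] output) whose columns are sample ids.
#' @param predictions Target-prediction pair tibble
#'   (see [read_target_pairs()]).
#' @param de_mirnas Character vector: the ancestry's refined miRNA signature.
#' @param de_genes Character vector: the ancestry's DE gene list.
#' @param samples Sample table covering both assays.
#' @param ancestry `"EA"` or `"AA"`.
#' @param alpha Significance threshold on the correlation p-value
#'   (default 0.05, inclusive).
#' @param exact_n Passed to [spearman_test()].
#' @return An edge tibble (`mirna_id`, `gene_id`, `rho`, `p`, `n`) of
#'   retained pairs, with attributes `n_pairs_tested`, `n_pairs_retained`,
#'   `n_pairs_skipped`.
#' @export
correlate_pairs <- function(mirna_expr, mrna_expr, predictions, de_mirnas,
                            de_genes, samples, ancestry, alpha = 0.05,
                            exact_n = 10) {
  check_enum(ancestry, ANCESTRY_LEVELS, "ancestry")
  check_scalar_number(alpha, "alpha", lower = 0, upper = 1)
  samples <- validate_sample_table(samples, allow_unpaired = TRUE)
  predictions <- validate_target_pairs(predictions)
  de_mirnas <- de_features(de_mirnas)
  de_genes <- de_features(de_genes)

  tum <- samples[samples$tissue == "tumor" & samples$ancestry == ancestry, ]
  mi_s <- tum[tum$assay == "miRNA" & tum$sample_id %in% colnames(mirna_expr), ]
  mr_s <- tum[tum$assay == "mRNA" & tum$sample_id %in% colnames(mrna_expr), ]
  patients <- sort(intersect(mi_s$patient_id, mr_s$patient_id))
  if (length(patients) == 0) {
    stopf("no tumor samples of ancestry %s shared between the miRNA and mRNA matrices",
          ancestry)
  }
  mi_cols <- mi_s$sample_id[match(patients, mi_s$patient_id)]
  mr_cols <- mr_s$sample_id[match(patients, mr_s$patient_id)]

  pairs <- predictions %>%
    dplyr::filter(.data$mirna_id %in% de_mirnas,
                  .data$gene_id %in% de_genes,
                  .data$mirna_id %in% rownames(mirna_expr),
                  .data$gene_id %in% rownames(mrna_expr))
  n_skipped <- 0L
  rows <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    xv <- mirna_expr[pairs$mirna_id[i], mi_cols]
    yv <- mrna_expr[pairs$gene_id[i], mr_cols]
    res <- tryCatch(spearman_test(xv, yv, exact_n = exact_n),
                    stratomir_constant_error = function(e) NULL)
    if (is.null(res)) {
      n_skipped <- n_skipped + 1L
      next
    }
    rows[[i]] <- tibble::tibble(
      mirna_id = pairs$mirna_id[i], gene_id = pairs$gene_id[i],
      rho = res$rho, p = res$p, n = res$n)
  }
  if (n_skipped > 0) {
    warnf("%d pair(s) skipped due to constant expression", n_skipped)
  }
  edges <- dplyr::bind_rows(rows)
  if (nrow(edges) == 0) {
    edges <- tibble::tibble(mirna_id = character(), gene_id = character(),
                            rho = numeric(), p = numeric(), n = integer())
  }
  retained <- edges[edges$p <= alpha, , drop = FALSE]
  attr(retained, "n_pairs_tested") <- nrow(pairs) - n_skipped
  attr(retained, "n_pairs_retained") <- nrow(retained)
  attr(retained, "n_pairs_skipped") <- n_skipped
  retained
}

#' Classify interaction edges as direct or indirect regulation
#'
#' Applies the sign rule used to read the correlation network: an inverse
#' correlation with the miRNA up and the target gene down in obese tumors is
#' a candidate direct post-transcriptional repression (`direct`); an inverse
#' correlation with the miRNA down and the gene up suggests loss of
#' miRNA-mediated control (`indirect`); positive correlations and inverse
#' correlations with concordant fold-change signs remain
#' `positive_unclassified` (a fold change of exactly zero never classifies).
#'
#' @param edges Edge tibble from [correlate_pairs()].
#' @param mirna_de,gene_de `de_table`s (or tibbles with `feature_id`,
#'   `log2_fc`) providing obese-vs-lean fold changes for every edge member.
#' @return The edge tibble with `mirna_log2fc`, `gene_log2fc` and
#'   `regulation_class` columns added.
#' @export
classify_edges <- function(edges, mirna_de, gene_de) {
  edges <- tibble::as_tibble(edges)
  if (nrow(edges) == 0) {
    return(dplyr::mutate(edges, mirna_log2fc = numeric(0),
                         gene_log2fc = numeric(0),
                         regulation_class = character(0)))
  }
  mfc <- stats::setNames(mirna_de$log2_fc, mirna_de$feature_id)
  gfc <- stats::setNames(gene_de$log2_fc, gene_de$feature_id)
  if (!all(edges$mirna_id %in% names(mfc))) {
    stopf("missing miRNA fold change for: %s",
          paste(setdiff(edges$mirna_id, names(mfc)), collapse = ", "))
  }
  if (!all(edges$gene_id %in% names(gfc))) {
    stopf("missing gene fold change for: %s",
          paste(setdiff(edges$gene_id, names(gfc)), collapse = ", "))
  }
  edges %>%
    dplyr::mutate(
      mirna_log2fc = unname(mfc[.data$mirna_id]),
      gene_log2fc = unname(gfc[.data$gene_id]),
      regulation_class = dplyr::case_when(
        .data$rho < 0 & .data$mirna_log2fc > 0 & .data$gene_log2fc < 0 ~ "direct",
        .data$rho < 0 & .data$mirna_log2fc < 0 & .data$gene_log2fc > 0 ~ "indirect",
        TRUE ~ "positive_unclassified"
      )
    )
}

#' Summarize an interaction network
#'
#' @param edges A (classified or unclassified) edge tibble.
#' @return A `network_summary` list: `n_edges`, `n_inverse` (rho < 0),
#'   `n_mirnas`, `n_genes`, and a `degree` tibble (node, role, degree,
#'   inverse_degree).
#' @export
network_summary <- function(edges) {
  edges <- tibble::as_tibble(edges)
  deg <- dplyr::bind_rows(
    edges %>% dplyr::group_by(node = .data$mirna_id) %>%
      dplyr::summarise(role = "miRNA", degree = dplyr::n(),
                       inverse_degree = sum(.data$rho < 0), .groups = "drop"),
    edges %>% dplyr::group_by(node = .data$gene_id) %>%
      dplyr::summarise(role = "gene", degree = dplyr::n(),
                       inverse_degree = sum(.data$rho < 0), .groups = "drop")
  )
  structure(list(
    n_edges = nrow(edges),
    n_inverse = sum(edges$rho < 0),
    n_mirnas = length(unique(edges$mirna_id)),
    n_genes = length(unique(edges$gene_id)),
    degree = deg
  ), class = "network_summary")
}

#' @export
print.network_summary <- function(x, ...) {
  cat(sprintf("miRNA-mRNA network: %d edges (%d inverse), %d miRNAs, %d genes\n",
              x$n_edges, x$n_inverse, x$n_mirnas, x$n_genes))
  invisible(x)
}

#' @export
tidy.network_summary <- function(x, ...) x$degree

#' @export
glance.network_summary <- function(x, ...) {
  tibble::tibble(n_edges = x$n_edges, n_inverse = x$n_inverse,
                 n_mirnas = x$n_mirnas, n_genes = x$n_genes)
}
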