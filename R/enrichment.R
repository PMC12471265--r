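#' Hypergeometric over-representation analysis
#'
#' For each gene set, tests whether the query list overlaps the set more
#' than expected by chance under sampling without replacement from the
#' universe: `p = P[X >= k]` with `X ~ Hypergeometric(N, K, n)` where `N` is
#' the universe size, `K` the set size within the universe, `n` the query
#' size within the universe and `k` the observed overlap. BH-FDR is computed
#' across all sets tested; the significance flag follows the raw
#' `p <= alpha` rule with the FDR reported alongside. Query ids outside the
#' universe are dropped with a warning.
#'
#' @param query Character vector of gene ids.
#' @param genesets Gene-set tibble (see [read_gmt()]).
#' @param universe Character vector: the background gene universe
#'   (typically all genes surviving the count filter).
#' @param alpha Raw-p significance threshold (default 0.05, inclusive).
#' @return An `enrichment` tibble sorted by p with columns `set_name`, `k`,
#'   `K`, `n`, `N`, `p`, `fdr`, `significant` and list-column `hit_ids`.
#' @export
hypergeom_enrich <- function(query, genesets, universe, alpha = 0.05) {
  universe <- unique(universe)
  if (length(universe) == 0) stopf("`universe` must be nonempty")
  query <- unique(query)
  outside <- setdiff(query, universe)
  if (length(outside) > 0) {
    warnf("%d query id(s) outside the universe dropped", length(outside))
    query <- intersect(query, universe)
  }
  if (length(query) == 0) {
    warnf("empty query after universe intersection")
    return(empty_enrichment())
  }
  N <- length(universe)
  n <- length(query)
  out <- purrr::map_dfr(seq_len(nrow(genesets)), function(i) {
    members <- intersect(unique(genesets$genes[[i]]), universe)
    hits <- intersect(query, members)
    K <- length(members)
    k <- length(hits)
    tibble::tibble(
      set_name = genesets$set_name[i],
      k = k, K = K, n = n, N = N,
      p = stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE),
      hit_ids = list(sort(hits))
    )
  })
  out$fdr <- bh_fdr(out$p)
  out$significant <- out$p <= alpha
  out <- out %>% dplyr::arrange(.data$p, .data$set_name) %>%
    dplyr::select("set_name", "k", "K", "n", "N", "p", "fdr",
                  "significant", "hit_ids")
  class(out) <- c("enrichment", class(out))
  out
}

empty_enrichment <- function() {
  out <- tibble::tibble(
    set_name = character(), k = integer(), K = integer(), n = integer(),
    N = integer(), p = numeric(), fdr = numeric(), significant = logical(),
    hit_ids = list())
  class(out) <- c("enrichment", class(out))
  out
}

#' Enrichment of correlated network target genes
#'
#' Runs [hypergeom_enrich()] with the distinct gene ids of an interaction
#' edge list as the query. The background universe is either the supplied
#' measured-gene universe (default, all genes surviving the mRNA count
#' filter) or the union of all gene-set members.
#'
#' @param edges Edge tibble from [correlate_pairs()]/[classify_edges()].
#' @param genesets Gene-set tibble.
#' @param universe Character vector of measured genes (required for
#'   `universe_mode = "all_measured_genes"`).
#' @param universe_mode `"all_measured_genes"` or `"geneset_union"`.
#' @param alpha Passed to [hypergeom_enrich()].
#' @return An `enrichment` tibble.
#' @export
enrich_network_targets <- function(edges, genesets, universe = NULL,
                                   universe_mode = "all_measured_genes",
                                   alpha = 0.05) {
  if (!universe_mode %in% c("all_measured_genes", "geneset_union")) {
    stopf("unknown universe_mode: %s", universe_mode,
          class = "stratomir_usage_error")
  }
  query <- unique(edges$gene_id)
  if (length(query) == 0) {
    warnf("empty edge list: no genes to enrich")
    return(empty_enrichment())
  }
  if (universe_mode == "geneset_union") {
    universe <- unique(unlist(genesets$genes))
  } else if (is.null(universe)) {
    stopf("`universe` is required for universe_mode = 'all_measured_genes'")
  }
  hypergeom_enrich(query, genesets, universe, alpha = alpha)
}
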