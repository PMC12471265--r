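#' Bundled synthetic example interaction networks
#'
#' Small, fully synthetic edge tables shaped like the ancestry-specific
#' obesity miRNA-mRNA networks this pipeline produces: the EA network has 41
#' edges (24 inverse) over 7 miRNAs and 39 unique genes, with miR-181b-5p
#' and miR-877-5p up in obese tumors and inversely correlated with
#' down-regulated targets (direct repression candidates) and miR-204-5p and
#' miR-143-3p down and inversely correlated with up-regulated targets
#' (indirect candidates); the AA network has 28 edges (17 inverse) over 17
#' miRNAs and 22 genes. Correlation and fold-change values are synthetic
#' placeholders consistent with the regulation classes; gene ids mix real
#' miRNA-target symbols with `SYNT*` synthetic fillers.
#'
#' @param ancestry `"EA"` or `"AA"`.
#' @return A list with `edges` (unclassified: `mirna_id`, `gene_id`, `rho`,
#'   `p`, `n`), `mirna_de` and `gene_de` (tibbles of `feature_id`,
#'   `log2_fc`) providing the obese-vs-lean fold changes needed by
#'   [classify_edges()].
#' @export
example_network <- function(ancestry = c("EA", "AA")) {
  ancestry <- match.arg(ancestry)
  if (ancestry == "EA") ea_example_network() else aa_example_network()
}

# helper: expand a mirna -> genes adjacency list into edge rows
adj_edges <- function(adj) {
  dplyr::bind_rows(lapply(names(adj), function(m) {
    tibble::tibble(mirna_id = m, gene_id = adj[[m]])
  }))
}

assemble_network <- function(inverse_adj, positive_adj, mirna_fc, gene_fc) {
  inv <- adj_edges(inverse_adj)
  pos <- adj_edges(positive_adj)
  inv$rho <- -0.55 - 0.01 * seq_len(nrow(inv))
  pos$rho <- 0.55 + 0.01 * seq_len(nrow(pos))
  edges <- dplyr::bind_rows(inv, pos)
  edges$p <- round(0.049 - 0.001 * (seq_len(nrow(edges)) %% 40), 4)
  edges$n <- 12L
  list(
    edges = edges,
    mirna_de = tibble::tibble(feature_id = names(mirna_fc),
                              log2_fc = unname(mirna_fc)),
    gene_de = tibble::tibble(feature_id = names(gene_fc),
                             log2_fc = unname(gene_fc))
  )
}

ea_example_network <- function() {
  inverse <- list(
    "miR-181b-5p" = c("HEY2", "CRYBG3", "ABI3BP", "KLHL29", "MCL1",
                      "PRICKLE2", "HAND2"),
    "miR-877-5p" = c("HAND2", "SORBS3", "ZBTB20"),
    "miR-204-5p" = c("GSPT1", "SEC61A2", "ANKRD13C", "RAB10", "TRIP12",
                     "RAB1A", "DR1"),
    "miR-143-3p" = c("PTBP3", "ZC3H15", "NCBP1", "PHTF2", "RSF1",
                     "SLC39A10", "GOLM1")
  )
  positive <- list(
    "miR-328-3p" = c("ESR1", "ESR2", "KRAS", "TNRC6C", "SYNTE01", "SYNTE02"),
    "miR-324-5p" = c("NCAN", "SH3BP5", "NBEA", "SYNTE03", "SYNTE04",
                     "SYNTE05"),
    "miR-10b-5p" = c("SYNTE06", "SYNTE07", "SYNTE08", "SYNTE09", "RAB1A")
  )
  up_mirnas <- c("miR-181b-5p" = 1.6, "miR-877-5p" = 1.2,
                 "miR-328-3p" = 0.9, "miR-324-5p" = 0.7, "miR-10b-5p" = 1.1)
  down_mirnas <- c("miR-204-5p" = -1.5, "miR-143-3p" = -1.1)
  down_genes <- unique(unlist(inverse[c("miR-181b-5p", "miR-877-5p")]))
  up_genes <- unique(unlist(inverse[c("miR-204-5p", "miR-143-3p")]))
  other_genes <- setdiff(unique(unlist(positive)), c(down_genes, up_genes))
  gene_fc <- c(
    stats::setNames(seq(-2.0, -1.2, length.out = length(down_genes)), down_genes),
    stats::setNames(seq(1.2, 2.0, length.out = length(up_genes)), up_genes),
    stats::setNames(seq(0.6, 1.4, length.out = length(other_genes)), other_genes)
  )
  assemble_network(inverse, positive, c(up_mirnas, down_mirnas), gene_fc)
}

aa_example_network <- function() {
  inverse <- list(
    "miR-195-5p" = c("STK33", "CLCN4"),
    "miR-454-3p" = "GADD45A",
    "miR-130a-3p" = c("GADD45A", "PLCB1"),
    "miR-301a-3p" = "FOSL1",
    "miR-148a-3p" = "CDC25B",
    "miR-424-5p" = c("CDC25B", "RASSF8", "AEBP2"),
    "miR-374a-5p" = c("RASSF8", "BIRC3"),
    "miR-199a-3p" = "AEBP2",
    "miR-199b-3p" = "AEBP2",
    "miR-30a-5p" = c("ADAM22", "SERPINE1"),
    "miR-376a-3p" = "ZFP69B"
  )
  positive <- list(
    "miR-381-3p" = "ERBB4",
    "miR-214-5p" = "ROBO2",
    "miR-190b" = "SYNTA01",
    "miR-19a-3p" = "SYNTA02",
    "miR-455-5p" = "SYNTA03",
    "miR-20a-5p" = "SYNTA04",
    "miR-195-5p" = "SYNTA05",
    "miR-424-5p" = "SYNTA06",
    "miR-130a-3p" = "SYNTA07",
    "miR-30a-5p" = "SYNTA08",
    "miR-454-3p" = "ERBB4"
  )
  mirnas <- unique(c(names(inverse), names(positive)))
  mirna_fc <- stats::setNames(seq(0.8, 1.8, length.out = length(mirnas)),
                              mirnas)
  inv_genes <- unique(unlist(inverse))
  pos_genes <- setdiff(unique(unlist(positive)), inv_genes)
  gene_fc <- c(
    stats::setNames(seq(-2.2, -1.1, length.out = length(inv_genes)), inv_genes),
    stats::setNames(seq(0.7, 1.5, length.out = length(pos_genes)), pos_genes)
  )
  assemble_network(inverse, positive, mirna_fc, gene_fc)
}
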