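#' Volcano plot of a differential-expression table
#'
#' @param object A `de_table`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.de_table <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$log2_fc,
                                       y = -log10(.data$p),
                                       colour = .data$is_de)) +
    ggplot2::geom_point(alpha = 0.6, size = 1) +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey60",
                                            `TRUE` = "firebrick")) +
    ggplot2::labs(x = "log2 fold change", y = "-log10 p",
                  colour = "called DE",
                  title = attr(object, "comparison")) +
    ggplot2::theme_minimal()
}

#' Dot plot of an enrichment table
#'
#' @param object An `enrichment` tibble.
#' @param top Number of top sets to display (default 20).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.enrichment <- function(object, top = 20, ...) {
  df <- utils::head(dplyr::arrange(object, .data$p), top)
  df$set_name <- factor(df$set_name, levels = rev(df$set_name))
  ggplot2::ggplot(df, ggplot2::aes(x = -log10(.data$p), y = .data$set_name,
                                   size = .data$k,
                                   colour = .data$significant)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = "-log10 p", y = NULL, size = "gene hits",
                  colour = "p <= alpha") +
    ggplot2::theme_minimal()
}

#' Bar chart of signature-set cardinalities
#'
#' @param object A `signature_sets` object.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.signature_sets <- function(object, ...) {
  df <- object$cardinality
  df$set <- factor(df$set, levels = rev(df$set))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$size, y = .data$set)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::geom_text(ggplot2::aes(label = .data$size), hjust = -0.2,
                       size = 3) +
    ggplot2::labs(x = "miRNAs", y = NULL,
                  title = "Signature subtraction chain") +
    ggplot2::theme_minimal()
}

#' Edge plot of a classified interaction network
#'
#' Displays each miRNA-gene edge as a tile coloured by Spearman rho and
#' annotated with its regulation class.
#'
#' @param edges A classified edge tibble.
#' @return A ggplot object.
#' @export
plot_network_edges <- function(edges) {
  ggplot2::ggplot(edges, ggplot2::aes(x = .data$gene_id, y = .data$mirna_id,
                                      fill = .data$rho)) +
    ggplot2::geom_tile() +
    ggplot2::geom_point(ggplot2::aes(shape = .data$regulation_class),
                        size = 1.5) +
    ggplot2::scale_fill_gradient2(low = "royalblue", mid = "white",
                                  high = "firebrick", limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Spearman rho",
                  shape = "class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5,
                                                       hjust = 1))
}
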