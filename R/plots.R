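#' Plot a fabric summary
#'
#' AVE (log10 scale) against REV per condition; one point per gene. The two
#' axes are independent characteristics, so structure here is biology, not
#' artifact.
#'
#' @param object A [fabric_summary()] tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot fabric_summary
#' @export
autoplot.fabric_summary <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$ave, y = .data$rev)) +
    ggplot2::geom_point(alpha = 0.5, size = 0.8) +
    ggplot2::scale_x_log10() +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::labs(x = "AVE (median units)", y = "REV (%)",
                  title = "Expression level vs. expression variability") +
    ggplot2::theme_minimal()
}

#' Plot classified gene-pair correlations as an adjacency grid
#'
#' Mirrors the square-matrix displays used for coordination analysis:
#' colored cells mark significantly synergistic / antagonistic /
#' independently expressed pairs; blank cells are not significant.
#'
#' @param object A [cor_pairs()] tibble (typically restricted to one gene
#'   set).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot cor_pairs
#' @export
autoplot.cor_pairs <- function(object, ...) {
  genes <- sort(unique(c(object$gene_a, object$gene_b)))
  sym <- bind_rows(
    object,
    rename(object, gene_a = "gene_b", gene_b = "gene_a")
  ) |>
    dplyr::filter(.data$klass != "not_significant")
  ggplot2::ggplot(sym, ggplot2::aes(
    x = factor(.data$gene_a, genes),
    y = factor(.data$gene_b, genes),
    fill = .data$klass
  )) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(
      synergistic = "#c0392b", antagonistic = "#2980b9",
      independent = "#f1c40f"
    )) +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "pair class") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5, hjust = 1))
}

#' Plot per-gene transcriptomic distances
#'
#' @param object A [trajectory_table()] tibble.
#' @param top Show only the `top` genes by TD (default 25).
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot trajectory_table
#' @export
autoplot.trajectory_table <- function(object, top = 25, ...) {
  sub <- object |>
    arrange(dplyr::desc(.data$td)) |>
    head(top)
  ggplot2::ggplot(sub, ggplot2::aes(
    x = stats::reorder(.data$gene, .data$td), y = .data$td
  )) +
    ggplot2::geom_col(fill = "#34495e") +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "transcriptomic distance (TD)",
                  title = unique(object$contrast)[1]) +
    ggplot2::theme_minimal()
}
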