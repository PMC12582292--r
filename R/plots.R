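#' Plot a correlation rank curve
#'
#' Scatter of Spearman rho against correlation rank for one analyte, with
#' highlighted genes labelled — the rank-plot view used to spot biosynthesis
#' genes among the top correlates of their product.
#'
#' @param table A `correlation_table`.
#' @param analyte Analyte name.
#' @param highlight_genes Genes to label.
#' @return A ggplot object.
#' @export
plot_rank_curve <- function(table, analyte, highlight_genes = character()) {
  rc <- rank_curve(table, analyte, highlight_genes)
  p <- ggplot2::ggplot(rc, ggplot2::aes(x = .data$rank, y = .data$rho)) +
    ggplot2::geom_point(size = 0.6, colour = "grey50") +
    ggplot2::labs(x = "correlation rank", y = "Spearman rho",
                  title = analyte) +
    ggplot2::theme_minimal()
  hl <- dplyr::filter(rc, .data$highlight)
  if (nrow(hl) > 0) {
    p <- p +
      ggplot2::geom_point(data = hl, colour = "firebrick", size = 2) +
      ggplot2::geom_text(data = hl, ggplot2::aes(label = .data$gene),
                         vjust = -0.8, size = 3, colour = "firebrick")
  }
  p
}

#' Plot a local-regression trend with its confidence band
#'
#' @param trend A `trend_curve` from [loess_trend()].
#' @param points Optional tibble with `conc`, `tpm` columns to overlay the
#'   raw cells.
#' @return A ggplot object.
#' @export
autoplot.trend_curve <- function(trend, points = NULL, ...) {
  p <- ggplot2::ggplot(trend, ggplot2::aes(x = .data$conc)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$fit - .data$ci_half_width,
                                      ymax = .data$fit + .data$ci_half_width),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(ggplot2::aes(y = .data$fit), colour = "steelblue") +
    ggplot2::labs(x = "concentration (uM)", y = "expression (TPM)") +
    ggplot2::theme_minimal()
  if (!is.null(points)) {
    p <- p + ggplot2::geom_point(data = points,
                                 ggplot2::aes(y = .data$tpm),
                                 size = 0.8, alpha = 0.6)
  }
  p
}

#' Plot an embedding coloured by a label
#'
#' @param ann An `annotation_table` (or any tibble with the embedding
#'   columns).
#' @param modality `"rna"` or `"met"`: which embedding and label to show.
#' @return A ggplot object.
#' @export
plot_embedding <- function(ann, modality = c("rna", "met")) {
  modality <- match.arg(modality)
  x <- paste0(modality, "_dim1")
  y <- paste0(modality, "_dim2")
  lab <- paste0(modality, "_label")
  ggplot2::ggplot(ann, ggplot2::aes(x = .data[[x]], y = .data[[y]],
                                    colour = .data[[lab]])) +
    ggplot2::geom_point(size = 1.2) +
    ggplot2::labs(x = "dim 1", y = "dim 2", colour = "label",
                  title = paste(toupper(modality), "embedding")) +
    ggplot2::theme_minimal()
}

#' Plot the annotation cross-tabulation
#'
#' Tile view of the RNA-label by metabolite-label contingency table (the
#' tabular equivalent of the annotation-comparison Sankey diagram).
#'
#' @param xt Output of [cross_tabulate()].
#' @return A ggplot object.
#' @export
plot_cross_tabulation <- function(xt) {
  ggplot2::ggplot(xt$table,
                  ggplot2::aes(x = .data$rna_label, y = .data$met_label,
                               fill = .data$n)) +
    ggplot2::geom_tile() +
    ggplot2::geom_text(ggplot2::aes(label = .data$n), colour = "white") +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = "RNA annotation", y = "metabolite annotation",
                  fill = "cells") +
    ggplot2::theme_minimal()
}

#' Plot a transporter-metabolite network
#'
#' Bipartite layout: analytes on one side, transporters on the other, edges
#' coloured by correlation sign.
#'
#' @param net A `transporter_network`.
#' @return A ggplot object.
#' @export
plot_transporter_network <- function(net) {
  analytes <- sort(unique(net$analyte))
  transporters <- sort(unique(net$transporter))
  pos <- dplyr::bind_rows(
    tibble::tibble(name = analytes, x = 0,
                   y = seq_along(analytes) / (length(analytes) + 1)),
    tibble::tibble(name = transporters, x = 1,
                   y = seq_along(transporters) / (length(transporters) + 1)))
  edges <- net |>
    dplyr::left_join(dplyr::rename(pos, x0 = "x", y0 = "y"),
                     by = c(analyte = "name")) |>
    dplyr::left_join(dplyr::rename(pos, x1 = "x", y1 = "y"),
                     by = c(transporter = "name"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(
      data = edges,
      ggplot2::aes(x = .data$x0, y = .data$y0, xend = .data$x1,
                   yend = .data$y1, colour = .data$sign),
      alpha = 0.6) +
    ggplot2::geom_point(data = pos, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_text(data = pos,
                       ggplot2::aes(.data$x, .data$y, label = .data$name),
                       hjust = rep(c(1.1, -0.1),
                                   c(length(analytes),
                                     length(transporters))),
                       size = 3) +
    ggplot2::scale_colour_manual(values = c(positive = "firebrick",
                                            negative = "steelblue")) +
    ggplot2::xlim(-0.5, 1.5) +
    ggplot2::theme_void()
}
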