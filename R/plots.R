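#' Plot a fitted seed-filling curve
#'
#' Observed dry weights with the fitted logistic curve and, on a secondary
#' panel-free overlay, nothing else — a minimal diagnostic plot.
#'
#' @param object A `filling_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.filling_fit <- function(object, ...) {
  grid <- tibble::tibble(dap = seq(min(object$times), max(object$times),
                                   length.out = 200))
  grid$weight_g <- logistic_weight(grid$dap, object$k, object$a, object$b)
  ggplot2::ggplot(augment(object), ggplot2::aes(x = .data$dap, y = .data$weight_g)) +
    ggplot2::geom_point() +
    ggplot2::geom_line(data = grid, colour = "forestgreen") +
    ggplot2::labs(x = "Days after pollination", y = "50-seed dry weight (g)",
                  subtitle = sprintf("k = %.3g g, b = %.3g /DAP, R² = %.3f",
                                     object$k, object$b, object$r_squared)) +
    ggplot2::theme_minimal()
}

#' LOD profile of a QTL scan
#'
#' @param scan A `qtl_scan` tibble (optionally with a `trait` column).
#' @param threshold Optional genome-wide LOD threshold drawn as a dashed line.
#' @return A ggplot object faceted by chromosome.
#' @export
plot_scan <- function(scan, threshold = NULL) {
  p <- ggplot2::ggplot(scan, ggplot2::aes(x = .data$cm, y = .data$lod)) +
    ggplot2::facet_grid(cols = ggplot2::vars(.data$chr), scales = "free_x",
                        space = "free_x") +
    ggplot2::labs(x = "Position (cM)", y = "LOD") +
    ggplot2::theme_minimal()
  p <- if ("trait" %in% names(scan)) {
    p + ggplot2::geom_line(ggplot2::aes(colour = .data$trait))
  } else {
    p + ggplot2::geom_line()
  }
  if (!is.null(threshold)) {
    p <- p + ggplot2::geom_hline(yintercept = threshold, linetype = "dashed")
  }
  p
}

#' Genome-wide bulked-segregant statistics
#'
#' Delta SNP index, G statistic and -log10 FDR q-value along the genome.
#'
#' @param site_stats Tibble from [bsa_site_stats()].
#' @return A ggplot object.
#' @export
plot_bsa <- function(site_stats) {
  d <- site_stats |>
    dplyr::mutate(neglog_q = -log10(pmax(.data$q, 1e-300))) |>
    tidyr::pivot_longer(c("delta_index", "g_stat", "neglog_q"),
                        names_to = "statistic", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$pos_bp / 1e6, y = .data$value)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$significant), size = 0.7) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$statistic),
                        cols = ggplot2::vars(.data$chr),
                        scales = "free", space = "free_x") +
    ggplot2::scale_colour_manual(values = c(`FALSE` = "grey55", `TRUE` = "red")) +
    ggplot2::labs(x = "Position (Mb)", y = NULL) +
    ggplot2::theme_minimal()
}

#' Volcano plot of the bulk expression contrast
#'
#' @param deg Tibble from [deg_filter()].
#' @return A ggplot object.
#' @export
plot_volcano <- function(deg) {
  ggplot2::ggplot(deg, ggplot2::aes(x = .data$log2fc,
                                    y = -log10(pmax(.data$padj, 1e-300)),
                                    colour = .data$direction)) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = "log2 fold change (high vs low pool)",
                  y = "-log10 adjusted p") +
    ggplot2::theme_minimal()
}
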