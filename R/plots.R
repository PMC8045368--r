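#' Plot sensitivity and PPV across a depth titration
#'
#' One panel per metric, lines per variant class x zygosity stratum, depth
#' on the x axis — the standard view of how concordance saturates with mean
#' sequencing depth.
#'
#' @param titration Tidy table from [depth_titration()].
#' @param metrics Metric columns to show.
#' @return A ggplot object.
#' @export
plot_depth_titration <- function(titration, metrics = c("sensitivity", "ppv")) {
  long <- titration %>%
    filter(.data$vclass != "all") %>%
    tidyr::pivot_longer(all_of(metrics), names_to = "metric") %>%
    mutate(stratum = paste(.data$vclass, .data$zygosity))
  ggplot2::ggplot(long, ggplot2::aes(.data$depth, .data$value,
                                     colour = .data$stratum)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric) +
    ggplot2::labs(x = "mean depth", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a miss-detection-index table
#'
#' @param object An `mdi_table` from [compute_mdi()].
#' @param ... Ignored.
#' @return A ggplot bar chart of MDI mass per depth.
#' @export
autoplot.mdi_table <- function(object, ...) {
  df <- as_tibble(object)
  df$depth_label <- factor(df$depth_label, levels = unique(df$depth_label))
  ggplot2::ggplot(df, ggplot2::aes(.data$depth_label, .data$mdi)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "mean depth", y = "miss detection index") +
    ggplot2::theme_minimal()
}

#' Plot per-bin CNV detection sensitivity across depths
#'
#' @param cells Sensitivity cells from [sensitivity_by_size()].
#' @return A ggplot object, one line per size bin, facetted by tool and
#'   call set.
#' @export
plot_size_sensitivity <- function(cells) {
  ggplot2::ggplot(
    filter(cells, !is.na(.data$sensitivity)),
    ggplot2::aes(as.numeric(.data$depth_label), .data$sensitivity,
                 colour = .data$size_bin)
  ) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_grid(tool ~ callset) +
    ggplot2::labs(x = "mean depth", y = "sensitivity", colour = "CNV size") +
    ggplot2::theme_minimal()
}

#' Plot a per-gene coverage report
#'
#' @param object A `coverage_report` from [gene_coverage()].
#' @param ... Ignored.
#' @return A ggplot dot chart of per-gene covered fraction, worst first.
#' @export
autoplot.coverage_report <- function(object, ...) {
  df <- arrange(object$per_gene, .data$fraction)
  df$gene <- factor(df$gene, levels = df$gene)
  ggplot2::ggplot(df, ggplot2::aes(.data$fraction, .data$gene)) +
    ggplot2::geom_point() +
    ggplot2::labs(x = paste0("fraction of exonic bases >= ", object$threshold, "X"),
                  y = NULL) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
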