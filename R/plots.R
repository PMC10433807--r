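#' Bar plot of mean transfer events per dyad by group
#'
#' Mirrors the study's group comparison figure: mean number of transfer
#' events per dyad with standard-deviation error bars, one bar per group.
#'
#' @param per_dyad tibble from [count_per_dyad()].
#' @param group grouping column (tidy-eval), e.g. `delivery_mode`.
#' @return a ggplot object.
#' @export
plot_transfer_counts <- function(per_dyad, group) {
  stats_df <- dplyr::summarise(
    dplyr::group_by(per_dyad, group = {{ group }}),
    mean = mean(.data$n_transfer_events),
    sd = stats::sd(.data$n_transfer_events), .groups = "drop")
  ggplot2::ggplot(stats_df, ggplot2::aes(x = .data$group, y = .data$mean)) +
    ggplot2::geom_col(fill = "grey70", colour = "black", width = 0.6) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = pmax(0, .data$mean - .data$sd),
                   ymax = .data$mean + .data$sd), width = 0.2) +
    ggplot2::labs(x = NULL, y = "Mean transfer events per dyad") +
    ggplot2::theme_classic()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Box plot of within- vs between-dyad pairwise values
#'
#' @param object a `dyad_partition` from [partition_by_dyad()].
#' @param ... unused.
#' @return a ggplot object (log10 y scale for SNP counts).
#' @export
autoplot.dyad_partition <- function(object, ...) {
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$side, y = .data$value,
                                        fill = .data$side)) +
    ggplot2::geom_boxplot(outlier.size = 0.6, show.legend = FALSE) +
    ggplot2::scale_fill_manual(values = c(within = "#d53e4f",
                                          between = "#3288bd")) +
    ggplot2::labs(x = NULL, y = object$metric) +
    ggplot2::theme_classic()
  if (object$metric == "snp_count" && all(df$value >= 0))
    p <- p + ggplot2::scale_y_continuous(
      trans = "log1p", breaks = c(0, 10, 100, 1000, 10000, 100000))
  p
}

#' Heatmap of a pairwise matrix
#'
#' @param object a `pairwise_matrix`.
#' @param ... unused.
#' @return a ggplot tile heatmap in the matrix's genome order.
#' @export
autoplot.pairwise_matrix <- function(object, ...) {
  ids <- rownames(object)
  df <- tibble::as_tibble(as.table(unclass(object)), .name_repair = "minimal")
  names(df) <- c("genome_a", "genome_b", "value")
  df$genome_a <- factor(df$genome_a, levels = ids)
  df$genome_b <- factor(df$genome_b, levels = rev(ids))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$genome_a, y = .data$genome_b,
                                   fill = .data$value)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = attr(object, "metric")) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}
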