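#' Scatter plot of a taxa embedding
#'
#' Clusters are coloured, noise points are grey, and flagged outliers are
#' drawn with an open ring.
#'
#' @param object An [embed_cluster()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.embedding_tbl <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$label <- factor(ifelse(df$cluster == -1L, "noise", as.character(df$cluster)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y, colour = .data$label)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_point(data = df[df$is_outlier, , drop = FALSE],
                        shape = 1, size = 4, colour = "black") +
    ggplot2::scale_colour_manual(
      values = c(noise = "grey60",
                 setNames(scales_hue(length(setdiff(levels(df$label), "noise"))),
                          setdiff(levels(df$label), "noise"))),
      name = "cluster") +
    ggplot2::labs(x = "UMAP 1", y = "UMAP 2") +
    ggplot2::theme_minimal()
}

scales_hue <- function(n) {
  if (n == 0L) return(character())
  grDevices::hcl(h = seq(15, 375, length.out = n + 1L)[seq_len(n)], l = 65, c = 100)
}

#' Log-log CCDF comparison plot
#'
#' @param object A [compare_ccdf()] result.
#' @param ... Unused.
#' @return A ggplot object (degree and CCDF on log10 axes; zero cells are
#'   dropped by the log scale).
#' @export
autoplot.ccdf_comparison <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df <- df[df$ccdf > 0 & df$degree > 0, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$degree, y = .data$ccdf,
                                   colour = .data$topology)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "degree", y = "CCDF") +
    ggplot2::theme_minimal()
}

#' Triad census bar chart
#'
#' @param object A [triad_census_signed()] result.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.triad_census <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$type, y = .data$percent,
                                   fill = .data$balanced)) +
    ggplot2::geom_col() +
    ggplot2::labs(x = "triangle type", y = "% of triangles", fill = "balanced") +
    ggplot2::theme_minimal()
}

#' Percolation trajectories
#'
#' @param object A [percolate()] trace.
#' @param metrics Which trace columns to draw.
#' @param ... Unused.
#' @return A ggplot object, one facet per metric.
#' @export
autoplot.percolation_trace <- function(object, metrics = c("giant_fraction", "n_components",
                                                           "density", "modularity"), ...) {
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$fraction_removed, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 1) +
    ggplot2::facet_wrap(~metric, scales = "free_y") +
    ggplot2::labs(x = "fraction of nodes removed") +
    ggplot2::theme_minimal()
}

#' Null metric distributions with the observed value marked
#'
#' @param object A [null_distributions()] tibble.
#' @param metrics Metrics to draw.
#' @param ... Unused.
#' @return A ggplot object: one facet per metric, histograms per topology,
#'   a vertical line at the observed network's value.
#' @export
autoplot.null_distributions <- function(object, metrics = c("degree_sd", "clustering",
                                                            "avg_path", "modularity",
                                                            "small_world"), ...) {
  reference <- attr(object, "reference", exact = TRUE)
  metrics <- intersect(metrics, names(object))
  df <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(dplyr::all_of(metrics), names_to = "metric", values_to = "value")
  ref <- tibble::tibble(metric = metrics,
                        value = vapply(metrics, function(m) reference[[m]][1L], numeric(1)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, fill = .data$topology)) +
    ggplot2::geom_histogram(alpha = 0.5, position = "identity", bins = 30) +
    ggplot2::geom_vline(data = ref, ggplot2::aes(xintercept = .data$value),
                        linetype = 2) +
    ggplot2::facet_wrap(~metric, scales = "free") +
    ggplot2::theme_minimal()
}
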