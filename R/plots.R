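#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot robustness trajectories of a subsampling study
#'
#' Mean criterion (with mean +/- sd error bars) per method across the
#' subsampling schedule; the x-axis is reversed so that reading left to right
#' follows the shrinking sample size. Simulation-mode studies default to the
#' two ratio metrics; real-data studies show the raw correlation.
#'
#' @param object A `subsample_result`.
#' @param metrics Metrics to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.subsample_result <- function(object,
                                      metrics = if (identical(attr(object, "mode"), "real_data")) {
                                        "rho"
                                      } else {
                                        c("rho_ratio", "pve_ratio")
                                      },
                                      ...) {
  df <- dplyr::filter(object, .data$metric %in% metrics)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$size, y = .data$mean, colour = .data$method
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.02
    ) +
    ggplot2::scale_x_reverse(breaks = sort(unique(df$size))) +
    ggplot2::facet_wrap(ggplot2::vars(.data$metric)) +
    ggplot2::labs(
      x = "sample size (subsampled from the master)",
      y = "mean over iterations", colour = "method"
    ) +
    ggplot2::theme_bw()
}

#' Plot a benchmark grid
#'
#' Fig-style panel of robustness trajectories: columns are sparsity levels,
#' rows are metrics, one line per method.
#'
#' @param object A `benchmark_result`.
#' @param metrics Metrics to display.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.benchmark_result <- function(object,
                                      metrics = c("rho_ratio", "pve_ratio"),
                                      ...) {
  df <- dplyr::filter(object, .data$metric %in% metrics)
  ggplot2::ggplot(df, ggplot2::aes(
    x = .data$size, y = .data$mean, colour = .data$method
  )) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      width = 0.02
    ) +
    ggplot2::scale_x_reverse(breaks = sort(unique(df$size))) +
    ggplot2::facet_grid(
      ggplot2::vars(.data$metric),
      ggplot2::vars(.data$alpha0),
      labeller = ggplot2::label_both
    ) +
    ggplot2::labs(
      x = "sample size", y = "mean over iterations",
      colour = "method"
    ) +
    ggplot2::theme_bw()
}

#' Plot the loading profile of a module summary
#'
#' Bar chart of per-node loadings, ordered by absolute contribution.
#'
#' @param object A `module_summary` with a loading (netshy / nonet / opt).
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.module_summary <- function(object, ...) {
  df <- tidy(object)
  if (nrow(df) == 0L) {
    abort("This summary has no loading to plot (hub method).",
      class = "netshy_invalid_argument"
    )
  }
  df$feature_id <- factor(df$feature_id, levels = df$feature_id[order(abs(df$loading))])
  ggplot2::ggplot(df, ggplot2::aes(x = .data$loading, y = .data$feature_id)) +
    ggplot2::geom_col() +
    ggplot2::labs(
      x = sprintf("loading (%s)", object$method), y = NULL
    ) +
    ggplot2::theme_bw()
}
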