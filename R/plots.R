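#' Plot a cell cycle map
#'
#' Scatter of the 2-D embedding, optionally colored by a per-cell
#' variable from a joined feature table.
#'
#' @param object A `cell_embedding`.
#' @param table Optional feature table joined on `cell_id`.
#' @param colour Optional column of `table` (or of the coordinates) to
#'   color by.
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.cell_embedding <- function(object, table = NULL, colour = NULL, ...) {
  df <- object$coords
  if (!is.null(table)) df <- left_join(df, table, by = "cell_id")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$map1, y = .data$map2))
  if (!is.null(colour)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour]]),
                                 size = 0.6, alpha = 0.8)
  } else {
    p <- p + ggplot2::geom_point(size = 0.6, alpha = 0.8)
  }
  p + ggplot2::coord_equal() +
    ggplot2::labs(x = "map-1", y = "map-2") +
    ggplot2::theme_minimal()
}

#' Heatmap of feature dynamics along a trajectory
#'
#' Binned mean intensities along pseudotime, features ordered by
#' hierarchical clustering of their dynamics ([order_features()]).
#'
#' @param object A `trajectory_profile`.
#' @param feature_order Optional explicit feature order; default
#'   [order_features()].
#' @param ... Ignored.
#' @return A ggplot.
#' @export
autoplot.trajectory_profile <- function(object, feature_order = NULL, ...) {
  long <- tidy(object)
  if (is.null(feature_order)) feature_order <- order_features(object)
  long$feature <- factor(long$feature, levels = rev(feature_order))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$pseudotime, y = .data$feature,
                                     fill = .data$mean_intensity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(name = "mean\nintensity") +
    ggplot2::labs(x = "diffusion pseudotime", y = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a biosensor trace
#'
#' CDK2 activity, p21 and the DNA proxy against time, with detected
#' S-phase intervals shaded.
#'
#' @param trace A trace tibble.
#' @param thresholds A [fate_thresholds()] (for S-phase shading).
#' @return A ggplot.
#' @export
plot_trace <- function(trace, thresholds = fate_thresholds()) {
  s_int <- detect_s_phase(trace, thresholds$foci_threshold)
  long <- trace %>%
    select("time_min", "cdk2_activity", "p21", "dna_proxy") %>%
    tidyr::pivot_longer(-"time_min", names_to = "channel") %>%
    mutate(time_h = .data$time_min / 60)
  p <- ggplot2::ggplot(long, ggplot2::aes(x = .data$time_h, y = .data$value))
  if (nrow(s_int) > 0) {
    p <- p + ggplot2::geom_rect(
      data = s_int %>% mutate(start_h = .data$start_min / 60,
                              end_h = .data$end_min / 60),
      ggplot2::aes(xmin = .data$start_h, xmax = .data$end_h,
                   ymin = -Inf, ymax = Inf),
      inherit.aes = FALSE, fill = "grey85"
    )
  }
  p + ggplot2::geom_line() +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y") +
    ggplot2::labs(x = "time (h)", y = NULL) +
    ggplot2::theme_minimal()
}
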