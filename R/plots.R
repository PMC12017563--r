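# ggplot2 helpers for the result objects.  Static counterparts of the
# interactive views a monitoring operator would use: acoustic maps,
# silhouette / contingency heat grids, trajectory ribbons, convergence
# curves.

#' @export
autoplot.reef_ensemble <- function(object, colour_by = NULL, `repeat` = 1,
                                   ...) {
  df <- tidy(object, repeats = `repeat`)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$dim1, y = .data$dim2))
  if (!is.null(colour_by) && colour_by %in% names(df)) {
    p <- p + ggplot2::geom_point(ggplot2::aes(colour = .data[[colour_by]]),
                                 size = 0.8, alpha = 0.8)
  } else {
    p <- p + ggplot2::geom_point(size = 0.8, alpha = 0.8)
  }
  p + ggplot2::labs(x = "dim 1", y = "dim 2",
                    title = paste0(object$method, " acoustic map (repeat ",
                                   `repeat`, ")"))
}

#' @export
autoplot.reef_silhouette <- function(object, ...) {
  df <- tidy(object)
  df2 <- df
  df2[c("category_a", "category_b")] <- df[c("category_b", "category_a")]
  both <- dplyr::bind_rows(df, df2)
  ggplot2::ggplot(both, ggplot2::aes(x = .data$category_a,
                                     y = .data$category_b,
                                     fill = .data$silhouette)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "navy", mid = "white",
                                  high = "firebrick", midpoint = 0.5,
                                  limits = c(-1, 1)) +
    ggplot2::labs(x = NULL, y = NULL,
                  title = paste("Pairwise silhouettes:", object$label_name)) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
autoplot.reef_contingency <- function(object, ...) {
  df <- tidy(object)
  df$cluster <- factor(df$cluster, levels = object$clusters)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$category, y = .data$cluster,
                                   fill = .data$percent)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "darkgreen",
                                 limits = c(0, 100)) +
    ggplot2::labs(x = "predefined category", y = "unsupervised cluster",
                  fill = "%") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' @export
autoplot.reef_trajectory <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$time,
                                       y = .data$median_rel_distance)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$decile_low,
                                      ymax = .data$decile_high),
                         alpha = 0.25) +
    ggplot2::geom_line() +
    ggplot2::facet_grid(replicate ~ group) +
    ggplot2::labs(x = NULL, y = "relative distance from starting point")
}

#' @export
autoplot.reef_convergence <- function(object, ...) {
  df <- tidyr::pivot_longer(
    object[!is.na(object$rel_mean_abs_diff),
           c("n", "rel_mean_abs_diff", "rel_max_abs_diff")],
    cols = -"n", names_to = "metric", values_to = "value")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$n, y = .data$value,
                                   colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "number of averaged repeats",
                  y = "relative difference of running average")
}
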