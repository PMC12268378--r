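#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Raster map of a grid field
#'
#' @param object A [grid_field()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot grid_field
#' @export
autoplot.grid_field <- function(object, ...) {
  df <- grid_cells(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = object$label) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (km)", y = "y (km)",
                  title = paste0(object$label, " surface")) +
    ggplot2::theme_minimal()
}

#' Scatter plot of a bivariate driver fit
#'
#' Replicates the driver-screening panel style: one point per county, the
#' OLS line and its confidence ribbon at the fit's level (default 90%).
#'
#' @param object An `airineq_ols` from [bivariate_ols()].
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot airineq_ols
#' @export
autoplot.airineq_ols <- function(object, ...) {
  df <- data.frame(x = object$fit$model$xv, y = object$fit$model$yv)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y)) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x,
                         level = object$conf_level, color = "firebrick") +
    ggplot2::labs(x = object$x, y = object$y,
                  subtitle = sprintf("R2 = %.2f, p = %.3g",
                                     object$r_squared, object$p_value)) +
    ggplot2::theme_minimal()
}

#' PCA biplot of the indicator decomposition
#'
#' @param object An `airineq_pca` from [run_pca()].
#' @param components Two components to display.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot airineq_pca
#' @export
autoplot.airineq_pca <- function(object, components = c("PC1", "PC2"), ...) {
  sc <- tibble::as_tibble(object$scores[, components, drop = FALSE])
  names(sc) <- c("c1", "c2")
  ld <- tibble::as_tibble(object$loadings[, components, drop = FALSE],
                          rownames = "indicator")
  names(ld) <- c("indicator", "l1", "l2")
  k <- max(abs(sc)) / max(abs(ld[, c("l1", "l2")]))
  r <- object$explained_variance_ratio[match(components,
                                             colnames(object$loadings))]
  ggplot2::ggplot(sc, ggplot2::aes(.data$c1, .data$c2)) +
    ggplot2::geom_point(alpha = 0.5) +
    ggplot2::geom_segment(data = ld,
                          ggplot2::aes(x = 0, y = 0, xend = .data$l1 * k,
                                       yend = .data$l2 * k),
                          arrow = ggplot2::arrow(length = ggplot2::unit(2, "mm")),
                          color = "firebrick", inherit.aes = FALSE) +
    ggplot2::geom_text(data = ld,
                       ggplot2::aes(x = .data$l1 * k * 1.08,
                                    y = .data$l2 * k * 1.08,
                                    label = .data$indicator),
                       color = "firebrick", size = 3, inherit.aes = FALSE) +
    ggplot2::labs(x = sprintf("%s (%.1f%%)", components[1], 100 * r[1]),
                  y = sprintf("%s (%.1f%%)", components[2], 100 * r[2])) +
    ggplot2::theme_minimal()
}

#' Edge diagram of a partial-correlation network
#'
#' Nodes on a circle; red edges are positive partial correlations, blue
#' negative, with width proportional to magnitude.
#'
#' @param object A `pc_network`.
#' @param ... Unused.
#' @return A ggplot.
#' @method autoplot pc_network
#' @export
autoplot.pc_network <- function(object, ...) {
  p <- length(object$labels)
  ang <- seq(0, 2 * pi, length.out = p + 1)[-(p + 1)]
  nodes <- tibble::tibble(node = object$labels,
                          x = cos(ang), y = sin(ang))
  edges <- tidy(object) |>
    dplyr::left_join(nodes, by = c(from = "node")) |>
    dplyr::rename(x0 = "x", y0 = "y") |>
    dplyr::left_join(nodes, by = c(to = "node"))
  ggplot2::ggplot() +
    ggplot2::geom_segment(data = edges,
                          ggplot2::aes(x = .data$x0, y = .data$y0,
                                       xend = .data$x, yend = .data$y,
                                       linewidth = abs(.data$weight),
                                       color = .data$weight > 0),
                          alpha = 0.7) +
    ggplot2::scale_color_manual(values = c(`TRUE` = "firebrick",
                                           `FALSE` = "steelblue"),
                                guide = "none") +
    ggplot2::scale_linewidth(range = c(0.2, 2), guide = "none") +
    ggplot2::geom_point(data = nodes, ggplot2::aes(.data$x, .data$y),
                        size = 8, color = "grey85") +
    ggplot2::geom_text(data = nodes,
                       ggplot2::aes(.data$x, .data$y, label = .data$node),
                       size = 2.5) +
    ggplot2::coord_equal() +
    ggplot2::theme_void()
}
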