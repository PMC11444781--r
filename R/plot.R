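# Band palette shared by the plotting helpers: the conventional colours for
# the pattern classes (undefined/uniform, spots, labyrinth, connected).
band_palette <- c(uniform = "white", spots = "#3B6FB6",
                  labyrinth = "#7A4FA3", connected = "#C0392B")

#' Heatmap of a lattice field
#'
#' @param field numeric matrix (e.g. [final_field()] or [make_pattern()]).
#' @param title optional plot title.
#' @return A ggplot object.
#' @export
plot_field <- function(field, title = NULL) {
  df <- tibble::tibble(
    row = as.vector(row(field)),
    col = as.vector(col(field)),
    value = as.vector(field)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(title = title, x = NULL, y = NULL, fill = "value") +
    ggplot2::theme_minimal()
}

#' @describeIn plot_field autoplot method for simulation results: heatmap of
#'   the final infected fraction.
#' @param object a `"contagion_sim"` object.
#' @param ... unused.
#' @export
autoplot.contagion_sim <- function(object, ...) {
  plot_field(final_field(object, as_fraction = TRUE),
             title = sprintf("final infected fraction (zeta=%g, alpha_I=%g, alpha_S=%g)",
                             object$config$zeta, object$config$alpha_I,
                             object$config$alpha_S))
}

#' Phase-diagram plot of an alpha-plane scan
#'
#' Tiles the risk-disposition plane, coloured by pattern band.
#'
#' @param object an `"alpha_scan"` result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.alpha_scan <- function(object, ...) {
  df <- tidy.alpha_scan(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$alpha_I, y = .data$alpha_S,
                                   fill = .data$band)) +
    ggplot2::geom_tile(colour = "grey80", linewidth = 0.1) +
    ggplot2::scale_fill_manual(values = band_palette, drop = FALSE) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(alpha[I]), y = expression(alpha[S]),
                  fill = "band",
                  title = sprintf("pattern bands at zeta = %g", object$zeta[1])) +
    ggplot2::theme_minimal()
}

#' Log-log plot of a zeta sweep
#'
#' Mean ACS against `zeta` with a +/- 1 SD ribbon, both axes logarithmic.
#' Rows with `zeta = 0` or undefined ACS are dropped from the plot.
#'
#' @param object a `"zeta_sweep"` result.
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.zeta_sweep <- function(object, ...) {
  df <- tidy.zeta_sweep(object)
  df <- df[df$zeta > 0 & !is.na(df$mean_acs), , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$zeta, y = .data$mean_acs)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = pmax(.data$mean_acs - .data$sd_acs, 1e-6),
                                      ymax = .data$mean_acs + .data$sd_acs),
                         alpha = 0.25, fill = "#3B6FB6") +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = expression(zeta), y = expression(mean ~ ACS ~ (hat(r)))) +
    ggplot2::theme_minimal()
}
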