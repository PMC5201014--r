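#' Plot a landmark-aligned density map
#'
#' Raster of the kernel density over the (s, r) half-plane with
#' cumulative-percentage contours and, when overlays are attached, the median
#' nuclear-envelope circle, the median nucleolus arc and the median landmark
#' positions.
#'
#' @param object a `density_map` (optionally with overlays from
#'   [median_overlays()] stored in `object$overlays`).
#' @param percentiles contour levels (cumulative percentage).
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.density_map <- function(object, percentiles = c(25, 50, 75), ...) {
  object <- as_percentile(object)
  df <- tidy(object)
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$s, y = .data$r)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$density)) +
    ggplot2::geom_contour(ggplot2::aes(z = .data$percentile),
                          breaks = percentiles, color = "white",
                          linewidth = 0.3) +
    ggplot2::scale_fill_viridis_c(name = "density") +
    ggplot2::coord_equal() +
    ggplot2::labs(
      x = "s (um, landmark at negative s)", y = "r (um)",
      title = sprintf("%s-aligned density map (n = %d points)",
                      object$landmark, object$n_points))
  ov <- object$overlays
  if (!is.null(ov)) {
    th <- seq(0, pi, length.out = 181)
    if (is.finite(ov$median_radius_um)) {
      env <- data.frame(s = ov$median_radius_um * cos(th),
                        r = ov$median_radius_um * sin(th))
      p <- p + ggplot2::geom_path(data = env, linetype = "dashed",
                                  color = "yellow")
    }
    if (is.finite(ov$nucleolus_radius_um)) {
      arc <- data.frame(s = ov$nucleolus_s + ov$nucleolus_radius_um * cos(th),
                        r = pmax(ov$nucleolus_r + ov$nucleolus_radius_um * sin(th - pi / 2), 0))
      p <- p + ggplot2::geom_path(data = arc, color = "red")
      p <- p + ggplot2::annotate("point", x = ov$nucleolus_s, y = ov$nucleolus_r,
                                 color = "red", size = 2)
    }
    if (is.finite(ov$spb_s %||% NA))
      p <- p + ggplot2::annotate("point", x = ov$spb_s, y = ov$spb_r,
                                 color = "orange", shape = 17, size = 2)
  }
  p
}

#' Plot the axial NPC density profile
#'
#' @param object an `axial_profile` tibble from [axial_density_profile()].
#' @param ... unused.
#' @return a ggplot object; the dashed line marks the isotropic expectation.
#' @export
autoplot.axial_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$theta_deg, y = .data$density)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::labs(x = "polar angle from anti-nucleolar pole (deg)",
                  y = "relative NPC density")
}

#' Plot an aberration model with its samples
#'
#' @param object an `aberration_model`.
#' @param samples optional tibble of (`x`, `d_over_R`) samples to show under
#'   the fitted polynomial.
#' @param ... unused.
#' @return a ggplot object.
#' @export
autoplot.aberration_model <- function(object, samples = NULL, ...) {
  xg <- seq(0, 1, length.out = 200)
  curve_df <- data.frame(x = xg, d_over_R = predict(object, xg))
  p <- ggplot2::ggplot(curve_df, ggplot2::aes(x = .data$x, y = .data$d_over_R))
  if (!is.null(samples)) {
    p <- p + ggplot2::geom_point(data = as.data.frame(samples),
                                 alpha = 0.1, size = 0.4)
  }
  p + ggplot2::geom_line(color = "red") +
    ggplot2::labs(x = "normalized axial coordinate |z - z_c| / R",
                  y = "d / R",
                  title = sprintf("d/R = %.3f x^2 + %.4f x + %.3f",
                                  object$a, object$b, object$c))
}

#' Plot cumulative frequency curves
#'
#' @param data tibble from [cumulative_frequency()], or a named list of such
#'   tibbles to overlay (names become the legend).
#' @param xlab x-axis label.
#' @return a ggplot object.
#' @export
plot_cumulative_frequency <- function(data, xlab = "value") {
  if (is.data.frame(data)) data <- list(all = data)
  df <- dplyr::bind_rows(data, .id = "group")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$value, y = .data$cumulative_percent,
                                   color = .data$group)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = xlab, y = "cumulative frequency (%)")
}
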