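#' Plot an empirical variogram with an optional fitted model
#'
#' Points show binned semivariance, sized by the number of pairs per
#' lag; the solid line is the fitted exponential model and the dashed
#' vertical line marks the distance at which it reaches 95% of the
#' total sill.
#'
#' @param emp A `wolb_variogram` from [empirical_variogram()].
#' @param fit Optional `wolb_variogram_fit`.
#' @return A ggplot object.
#' @export
plot_variogram <- function(emp, fit = NULL) {
  p <- ggplot2::ggplot(
    as_tibble(emp),
    ggplot2::aes(x = .data$lag_center, y = .data$gamma_hat)
  ) +
    ggplot2::geom_point(ggplot2::aes(size = .data$n_pairs), alpha = 0.7) +
    ggplot2::scale_size_area(name = "pairs") +
    ggplot2::labs(
      x = "separation distance (km)",
      y = "semivariance of infection frequency"
    ) +
    ggplot2::theme_minimal()
  if (!is.null(fit) && fit$range_identifiable) {
    r <- seq(1e-6, max(emp$lag_center), length.out = 200)
    line <- tibble(r = r, gamma = exponential_gamma(fit, r))
    p <- p +
      ggplot2::geom_line(
        data = line, ggplot2::aes(x = .data$r, y = .data$gamma),
        inherit.aes = FALSE
      ) +
      ggplot2::geom_vline(
        xintercept = practical_range(fit)$range95,
        linetype = "dashed"
      )
  }
  p
}

#' @rdname plot_variogram
#' @param object A `wolb_variogram_fit`.
#' @param ... Unused.
#' @method autoplot wolb_variogram_fit
#' @export
autoplot.wolb_variogram_fit <- function(object, ...) {
  plot_variogram(object$empirical, object)
}

#' Plot a kriged surface
#'
#' Tile map of predicted infection frequency (or kriging variance) over
#' the prediction grid.
#'
#' @param object A `wolb_surface` from [predict_grid()].
#' @param what `"z_hat"` (default) or `"krig_var"`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wolb_surface
#' @export
autoplot.wolb_surface <- function(object, what = c("z_hat", "krig_var"), ...) {
  what <- match.arg(what)
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$lon, y = .data$lat, fill = .data[[what]])
  ) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(
      name = if (what == "z_hat") "predicted\nfrequency" else "kriging\nvariance"
    ) +
    ggplot2::coord_quickmap() +
    ggplot2::labs(x = "longitude", y = "latitude") +
    ggplot2::theme_minimal()
}

#' Diagnostic plot for leave-one-out cross-validation
#'
#' Observed versus predicted values with the 1:1 line.
#'
#' @param object A `wolb_loocv` from [loocv()].
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot wolb_loocv
#' @export
autoplot.wolb_loocv <- function(object, ...) {
  ggplot2::ggplot(
    as_tibble(object),
    ggplot2::aes(x = .data$observed, y = .data$predicted)
  ) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed") +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::labs(
      x = "observed infection frequency",
      y = "leave-one-out prediction"
    ) +
    ggplot2::theme_minimal()
}
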