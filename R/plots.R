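#' Plot a Z-spectrum
#'
#' Offset axis reversed (downfield left), the CEST convention.
#'
#' @param object A Z-spectrum tibble.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.zspec <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$offset_ppm, y = .data$z)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "saturation offset (ppm)", y = expression(M[z] / M[0])) +
    ggplot2::theme_minimal()
}

#' Plot a fitted Z-spectrum with residuals
#'
#' Data points, fitted curve, and the signed residuals in a lower panel.
#'
#' @param object A `zspec_fit`.
#' @param ... Unused.
#' @return A ggplot (faceted data/residual panels).
#' @export
autoplot.zspec_fit <- function(object, ...) {
  res <- object$residuals
  long <- dplyr::bind_rows(
    tibble(offset_ppm = res$offset_ppm, value = res$z, what = "data",
           panel = "Z-spectrum"),
    tibble(offset_ppm = res$offset_ppm, value = res$fitted, what = "fit",
           panel = "Z-spectrum"),
    tibble(offset_ppm = res$offset_ppm, value = res$resid, what = "residual",
           panel = "residuals")
  )
  long$panel <- factor(long$panel, levels = c("Z-spectrum", "residuals"))
  ggplot2::ggplot(long, ggplot2::aes(x = .data$offset_ppm, y = .data$value,
                                     colour = .data$what)) +
    ggplot2::geom_point(data = ~ dplyr::filter(.x, .data$what != "fit"),
                        size = 0.8) +
    ggplot2::geom_line(data = ~ dplyr::filter(.x, .data$what == "fit")) +
    ggplot2::facet_grid(rows = ggplot2::vars(.data$panel), scales = "free_y") +
    ggplot2::scale_x_reverse() +
    ggplot2::labs(x = "saturation offset (ppm)", y = NULL, colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot an exchange-rate robustness curve
#'
#' Mean absolute glutamate error against the generating exchange rate.
#'
#' @param object A tibble from [robustness_study()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.robustness_curve <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$true_kex_hz,
                                       y = .data$mean_abs_err_pct)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(
      x = sprintf("true k_ex^%s (Hz)", object$param[1]),
      y = "mean |[Glu] error| (%)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot the error distribution of a recovery study
#'
#' Histogram of relative glutamate estimation errors, one panel per noise
#' level.
#'
#' @param object A `glu_study` from [accuracy_precision_study()].
#' @param binwidth Histogram bin width (percent).
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.glu_study <- function(object, binwidth = 0.25, ...) {
  d <- dplyr::filter(object$draws, .data$converged)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$rel_err_pct)) +
    ggplot2::geom_histogram(binwidth = binwidth, fill = "grey40") +
    ggplot2::facet_wrap(~sigma, labeller = ggplot2::label_both) +
    ggplot2::labs(x = "[Glu] relative error (%)", y = "count") +
    ggplot2::theme_minimal()
}

#' Display a parametric map
#'
#' @param object A [parametric_map()].
#' @param slice Slice index to display.
#' @param ... Unused.
#' @return A ggplot raster of the selected slice.
#' @export
autoplot.parametric_map <- function(object, slice = 1, ...) {
  v <- object$values[, , slice]
  d <- tibble(x = rep(seq_len(nrow(v)), ncol(v)),
              y = rep(seq_len(ncol(v)), each = nrow(v)),
              value = as.vector(v))
  ggplot2::ggplot(d, ggplot2::aes(x = .data$x, y = .data$y,
                                  fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::coord_equal() +
    ggplot2::scale_fill_viridis_c(na.value = "black", name = object$label) +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
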