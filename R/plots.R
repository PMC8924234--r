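#' Plot a rendered display
#'
#' @param object A [display_spec()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.display_spec <- function(object, ...) {
  img <- render_display(object)
  df <- tidyr::expand_grid(x = 0:(nrow(img) - 1), y = 0:(ncol(img) - 1))
  df$lum <- as.numeric(unclass(img))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$lum)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 1), guide = "none") +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = paste0(object$configuration, ", n = ",
                                 object$numerosity)) +
    ggplot2::theme_void()
}

#' Plot a radial power spectrum with its first-harmonic limit
#'
#' @param object A [radial_psd()] tibble.
#' @param f1 Optional first-harmonic limit to mark (computed when missing).
#' @param ... Passed to [first_harmonic_limit()].
#' @return A ggplot.
#' @export
autoplot.radial_psd <- function(object, f1 = NULL, ...) {
  if (is.null(f1)) f1 <- first_harmonic_limit(object, ...)
  ggplot2::ggplot(object, ggplot2::aes(.data$frequency, .data$psd)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = f1, linetype = "dashed",
                        colour = "red") +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "spatial frequency (cycles/image)",
                  y = "power spectral density",
                  subtitle = paste("first-harmonic limit:", f1,
                                   "cycles/image")) +
    ggplot2::theme_minimal()
}

#' Mean aggregate power against numerosity
#'
#' @param power_by_n Tibble with `numerosity`, `mean_power` and optionally
#'   `configuration`.
#' @return A ggplot on log-log axes.
#' @export
plot_power_numerosity <- function(power_by_n) {
  aes <- if ("configuration" %in% names(power_by_n)) {
    ggplot2::aes(.data$numerosity, .data$mean_power,
                 colour = .data$configuration)
  } else {
    ggplot2::aes(.data$numerosity, .data$mean_power)
  }
  ggplot2::ggplot(power_by_n, aes) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::scale_y_log10() +
    ggplot2::labs(x = "numerosity",
                  y = "normalized aggregate Fourier power") +
    ggplot2::theme_minimal()
}

#' Plot an eccentricity profile fit with its bootstrap envelope
#'
#' @param object An `eccentricity_profile_fit`.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.eccentricity_profile_fit <- function(object, ...) {
  ggplot2::ggplot(object$bins,
                  ggplot2::aes(.data$bin_center, .data$mean_ve)) +
    ggplot2::geom_ribbon(data = object$ci_curves,
                         ggplot2::aes(x = .data$eccentricity,
                                      ymin = .data$lower,
                                      ymax = .data$upper),
                         inherit.aes = FALSE, alpha = 0.2) +
    ggplot2::geom_pointrange(ggplot2::aes(
      ymin = .data$mean_ve - .data$sem_ve,
      ymax = .data$mean_ve + .data$sem_ve)) +
    ggplot2::geom_line(data = object$ci_curves,
                       ggplot2::aes(x = .data$eccentricity,
                                    y = .data$median),
                       inherit.aes = FALSE, colour = "blue") +
    ggplot2::labs(x = "pRF eccentricity (deg)",
                  y = "variance explained",
                  subtitle = paste(object$family, "profile fit")) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
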