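#' Plot a fitted Arrhenius law over the measurements
#'
#' Measured rates (with SD error bars where available) and the fitted
#' curve on a log rate scale against temperature.
#'
#' @param object An `arrhenius_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot arrhenius_fit
#' @export
autoplot.arrhenius_fit <- function(object, ...) {
  d <- object$data
  d$rate <- convert_rate(d$rate_pct_per_min, object$unit)
  Tk <- seq(min(d$temperature_K) - 5, max(d$temperature_K) + 5, length.out = 100)
  curve <- tibble(temperature_K = Tk, rate = predict(object, Tk))
  p <- ggplot2::ggplot(d, ggplot2::aes(x = .data$temperature_K, y = .data$rate)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::geom_line(data = curve, colour = "steelblue") +
    ggplot2::labs(
      x = "Temperature (K)", y = paste0("Hydrolysis rate (", object$unit, ")"),
      title = if (!is.na(object$compound)) paste("Arrhenius fit:", object$compound)
    )
  if ("sd_pct_per_min" %in% names(d)) {
    d$sd <- convert_rate(d$sd_pct_per_min, object$unit)
    p <- p + ggplot2::geom_errorbar(
      data = d,
      ggplot2::aes(ymin = pmax(.data$rate - .data$sd, 0), ymax = .data$rate + .data$sd),
      width = 1
    )
  }
  p
}

#' Plot class-conditional sweep summaries
#'
#' ATP consumption flux, NAD production flux and their ratio against
#' temperature, one line per pathway class — the tabular counterpart of
#' the study's flux-versus-temperature panels.
#'
#' @param object A `nad_sweep`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nad_sweep
#' @export
autoplot.nad_sweep <- function(object, ...) {
  d <- object$class_summary %>%
    tidyr::pivot_longer(c("mean_J_ATP", "mean_J_NAD", "mean_ratio"),
                        names_to = "quantity", values_to = "value")
  ggplot2::ggplot(d, ggplot2::aes(x = .data$temperature_K, y = .data$value,
                                  colour = .data$classification)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::facet_wrap(~quantity, scales = "free_y") +
    ggplot2::labs(x = "Temperature (K)", y = NULL,
                  title = paste("Temperature sweep:", object$objective))
}

#' Heatmap of concentration control coefficients
#'
#' @param object A `nad_mca`.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot nad_mca
#' @export
autoplot.nad_mca <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$process, y = .data$species,
                                       fill = .data$coefficient)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(low = "firebrick", mid = "white", high = "navy") +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1)) +
    ggplot2::labs(x = "Perturbed process", y = "Species",
                  fill = "C")
}
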