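#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @export
autoplot.psychometric_fit <- function(object, ...) {
  agg <- dplyr::mutate(object$data,
                       frac = .data$wins / (.data$wins + .data$losses))
  grid <- tibble::tibble(coherence = seq(min(agg$coherence),
                                         max(agg$coherence), length.out = 200))
  b <- object$coefficients
  grid$p <- stats::plogis(b[1] + b[2] * grid$coherence)
  ggplot2::ggplot(agg, ggplot2::aes(x = .data$coherence)) +
    ggplot2::geom_point(ggplot2::aes(y = .data$frac,
                                     size = .data$wins + .data$losses),
                        alpha = 0.7) +
    ggplot2::geom_line(data = grid, ggplot2::aes(y = .data$p)) +
    ggplot2::scale_size_area(name = "trials", max_size = 3) +
    ggplot2::labs(x = "coherence", y = "P(P1 wins)",
                  title = sprintf("bias %.1f%%, sensitivity %.2f",
                                  object$bias, object$sensitivity)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.rate_timeseries <- function(object, ...) {
  ggplot2::ggplot(object$population,
                  ggplot2::aes(x = .data$t_s, y = .data$rate,
                               colour = .data$population)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "population rate (spk/s)") +
    ggplot2::theme_minimal()
}

#' Raster plot of a trial
#'
#' @param recording A `wta_trial`.
#' @param populations Populations to include.
#' @return A ggplot object.
#' @export
plot_raster <- function(recording, populations = c("P1", "P2")) {
  sp <- recording$spikes[recording$spikes$population %in% populations, ]
  ggplot2::ggplot(sp, ggplot2::aes(x = .data$t_ms / 1e3,
                                   y = .data$neuron_id,
                                   colour = .data$population)) +
    ggplot2::geom_point(shape = ".", alpha = 0.8) +
    ggplot2::labs(x = "time (s)", y = "neuron") +
    ggplot2::theme_minimal()
}

#' Per-neuron task firing rate vs distance to the electrode
#'
#' @param per_neuron `per_neuron` tibble from [variant_experiment()].
#' @return A ggplot object.
#' @export
plot_activation_profile <- function(per_neuron) {
  ggplot2::ggplot(per_neuron, ggplot2::aes(x = .data$distance_um,
                                           y = .data$rate)) +
    ggplot2::geom_point() +
    ggplot2::scale_x_log10() +
    ggplot2::labs(x = "distance to electrode (um)",
                  y = "task firing rate (spk/s)") +
    ggplot2::theme_minimal()
}
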