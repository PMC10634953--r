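#' Plot a simulation record
#'
#' Spike raster with the population firing rate overlaid below.
#'
#' @param object A `sim_record`.
#' @param bin Rate histogram bin (ms).
#' @param ... Unused.
#' @returns A ggplot object.
#' @export
autoplot.sim_record <- function(object, bin = 20, ...) {
  rate <- population_rate(object, bin = bin)
  raster <- object$spikes
  scale <- object$n / max(rate$rate, 1e-9)
  ggplot2::ggplot() +
    ggplot2::geom_point(
      data = raster,
      ggplot2::aes(x = .data$time / 1000, y = .data$neuron),
      shape = ".", alpha = 0.6
    ) +
    ggplot2::geom_line(
      data = rate,
      ggplot2::aes(x = .data$time / 1000, y = .data$rate * scale),
      colour = "firebrick"
    ) +
    ggplot2::scale_y_continuous(
      "neuron",
      sec.axis = ggplot2::sec_axis(~ . / scale, name = "rate (Hz)")
    ) +
    ggplot2::labs(x = "time (s)") +
    ggplot2::theme_minimal()
}

#' Plot a burst-capability map
#'
#' @param object A `capability_map` tibble from [map_capability_region()].
#' @param ... Unused.
#' @returns A ggplot object.
#' @export
autoplot.capability_map <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$g_nap, y = .data$g_leak,
                                       fill = .data$capable)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey85",
                                          `TRUE` = "firebrick")) +
    ggplot2::labs(x = "g_NaP (nS)", y = "g_Leak (nS)",
                  fill = "burst-capable") +
    ggplot2::theme_minimal()
}

#' Plot an uncoupled activity-mode profile
#'
#' Activity label (silent, bursting, tonic) against tonic drive for one
#' neuron.
#'
#' @param object A `capability_profile` from
#'   [classify_burst_capability()].
#' @param ... Unused.
#' @returns A ggplot object.
#' @export
autoplot.capability_profile <- function(object, ...) {
  ggplot2::ggplot(object$modes,
                  ggplot2::aes(x = .data$g_tonic, y = .data$label,
                               colour = .data$label)) +
    ggplot2::geom_point(size = 2, show.legend = FALSE) +
    ggplot2::labs(x = "g_Tonic (nS)", y = NULL) +
    ggplot2::theme_minimal()
}
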