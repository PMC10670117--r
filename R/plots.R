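# ggplot2 views of the main result types.

#' Raster plot of a simulation
#'
#' Spike times per neuron, colored by population (pyramidal, OLM, basket).
#'
#' @param sim a `ca3_sim` or a spikes tibble.
#' @param window optional time window (ms).
#' @export
plot_raster <- function(sim, window = NULL) {
  spikes <- if (inherits(sim, "ca3_sim")) sim$spikes else sim
  if (!is.null(window)) {
    spikes <- spikes[spikes$time >= window[1] & spikes$time <= window[2], ]
  }
  ggplot2::ggplot(spikes, ggplot2::aes(.data$time, .data$cell,
                                       colour = .data$population)) +
    ggplot2::geom_point(size = 0.2, shape = 16) +
    ggplot2::labs(x = "time (ms)", y = "neuron", colour = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.psd <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$frequency, .data$power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "frequency (Hz)", y = "power density") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.lfp_trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time, .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::labs(x = "time (ms)", y = "LFP (mV)") +
    ggplot2::theme_minimal()
}

#' Grid summary plot: delta-gamma against the scaling factors
#'
#' @param grid output of [run_grid()].
#' @export
plot_grid_results <- function(grid) {
  long <- tidyr::pivot_longer(grid, c("krec", "kext"),
                              names_to = "factor", values_to = "level")
  ggplot2::ggplot(long, ggplot2::aes(.data$level, .data$delta_gamma)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se, geom = "pointrange") +
    ggplot2::facet_wrap(~factor) +
    ggplot2::labs(x = "scaling level", y = expression(Delta * gamma)) +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
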