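regime_palette <- c(
  "red" = "#d62728", "orange" = "#ff7f0e", "yellow" = "#e6c700",
  "blue" = "#1f77b4", "light blue" = "#9ecae1", "dark blue" = "#08306b",
  "purple" = "#9467bd", "green" = "#2ca02c", "cyan" = "#17becf",
  "unlisted" = "grey70"
)

#' Plot a regime map
#'
#' Tile plot of the `(F_GO, F_MO)` plane coloured by the regime color key.
#'
#' @param object a `regime_map` from [run_sweep()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.regime_map <- function(object, ...) {
  df <- tibble::as_tibble(object)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$F_GO, y = .data$F_MO,
                                   fill = .data$color)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_manual(values = regime_palette, na.value = "white") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = expression(F[GO] ~ "(rad/s)"),
                  y = expression(F[MO] ~ "(rad/s)"),
                  fill = "regime",
                  title = "Synchronization regimes") +
    ggplot2::theme_minimal()
}

#' Plot the collective order of a simulated run
#'
#' Shows the Kuramoto order parameter of each network and the modified
#' two-network order parameter over time.
#'
#' @param object a `phase_series` from [integrate_model()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.phase_series <- function(object, ...) {
  df <- dplyr::bind_rows(
    dplyr::mutate(network_order(object, "go")[c("time", "r")],
                  series = "r (glycolysis)"),
    dplyr::mutate(network_order(object, "mo")[c("time", "r")],
                  series = "r (OXPHOS)"),
    dplyr::mutate(dplyr::rename(modified_order(object), r = "s"),
                  series = "s (both networks)")
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time, y = .data$r,
                                   colour = .data$series)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time (s)", y = "order parameter", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a HeLa-scenario output
#'
#' The modified order parameter `s(t)` over the full scenario, the model
#' output comparable to measured single-cell NADH fluorescence.
#'
#' @param object a `hela_series` from [run_hela()].
#' @param ... unused.
#' @return A ggplot object.
#' @export
autoplot.hela_series <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$time, y = .data$s)) +
    ggplot2::geom_line(linewidth = 0.3, colour = "#1f77b4") +
    ggplot2::ylim(0, 1) +
    ggplot2::labs(x = "time (s)", y = "modified order parameter s",
                  title = "Simulated collective metabolic amplitude") +
    ggplot2::theme_minimal()
}
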