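#' Plot ASI traces
#'
#' Normalised (or raw-count) average spontaneous ignition traces per area,
#' aligned at event onset.
#'
#' @param object A `ca_asi` tibble.
#' @param normalised Plot the normalised traces (fraction of CA cells,
#'   default) or raw active-cell counts.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ca_asi
#' @export
autoplot.ca_asi <- function(object, normalised = TRUE, ...) {
  d <- tibble::as_tibble(object)
  d$y <- if (normalised) d$norm else d$count
  d <- dplyr::summarise(dplyr::group_by(d, .data$area, .data$step),
                        y = mean(.data$y), .groups = "drop")
  d$area <- factor(d$area, levels = AREA_NAMES)
  ggplot2::ggplot(d, ggplot2::aes(.data$step, .data$y, colour = .data$area)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "time-step relative to ignition onset",
      y = if (normalised) "fraction of CA cells active" else "active CA cells",
      colour = "area",
      title = "Average spontaneous ignition (ASI)"
    ) +
    ggplot2::theme_minimal()
}

#' Plot detected ignition events
#'
#' One horizontal segment per ignition episode, by CA.
#'
#' @param object A `ca_events` tibble.
#' @param ... Unused.
#' @return A ggplot object.
#' @method autoplot ca_events
#' @export
autoplot.ca_events <- function(object, ...) {
  d <- tibble::as_tibble(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$onset, xend = .data$offset,
                                  y = factor(.data$pattern),
                                  yend = factor(.data$pattern))) +
    ggplot2::geom_segment(linewidth = 2) +
    ggplot2::labs(x = "simulation step", y = "cell assembly",
                  title = "Spontaneous ignition events") +
    ggplot2::theme_minimal()
}

#' Plot per-area mean CA size across gamma
#'
#' @param sizes A tibble from [ca_size_table()].
#' @return A ggplot object.
#' @export
plot_ca_sizes <- function(sizes) {
  sizes$area <- factor(sizes$area, levels = AREA_NAMES)
  ggplot2::ggplot(sizes, ggplot2::aes(.data$area, .data$mean_size,
                                      fill = .data$centrality)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~gamma, scales = "free_y") +
    ggplot2::labs(x = "area", y = "mean CA size (cells)",
                  title = "Cell-assembly size by area and membership fraction") +
    ggplot2::theme_minimal()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
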