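# ggplot2 views of the pipeline's result types.

#' Plot a raw acceleration trace
#'
#' Line plot of the three axes over time, facetted by axis.
#'
#' @param object A [raw_accel()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.raw_accel <- function(object, ...) {
  long <- tibble::as_tibble(object) |>
    tidyr::pivot_longer(cols = c("x", "y", "z"), names_to = "axis",
                        values_to = "acceleration_g")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$time,
                                     y = .data$acceleration_g)) +
    ggplot2::geom_line(linewidth = 0.2) +
    ggplot2::facet_wrap(~axis, ncol = 1) +
    ggplot2::labs(title = attr(object, "record_id"),
                  x = "time (s)", y = "acceleration (g)")
}

#' Plot per-second activity counts
#'
#' @param counts A wide tibble from [activity_counts()].
#' @param axes Which series to draw.
#' @return A ggplot.
#' @export
plot_counts <- function(counts, axes = c("x", "y", "z", "vm")) {
  long <- counts |>
    tidyr::pivot_longer(cols = dplyr::any_of(axes), names_to = "axis",
                        values_to = "counts")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$second, y = .data$counts,
                                     colour = .data$axis)) +
    ggplot2::geom_step() +
    ggplot2::labs(x = "second", y = "counts / s", colour = "axis")
}

#' Heatmap of an agreement table
#'
#' Tiles the ICC for each speed and equation; the MEAN summary row is
#' omitted.
#'
#' @param object An `ee_agreement` from [agreement_table()].
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.ee_agreement <- function(object, ...) {
  long <- tidy(object) |>
    dplyr::filter(.data$speed != "MEAN") |>
    dplyr::mutate(
      speed = factor(.data$speed, levels = unique(.data$speed)),
      label = paste0(ifelse(.data$corrected, "corr. ", ""), .data$equation)
    )
  ggplot2::ggplot(long, ggplot2::aes(x = .data$label, y = .data$speed,
                                     fill = .data$icc)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1), low = "#b2182b",
                                  mid = "white", high = "#2166ac") +
    ggplot2::labs(x = NULL, y = "speed (km/h)",
                  fill = sprintf("ICC (%s)", attr(object, "icc_form")),
                  title = sprintf("Agreement: %s", attr(object, "contrast"))) +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
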