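# ggplot2 displays for the main result types

#' Plot an axial slice of a connectivity map
#'
#' @param object A `connectivity_map`.
#' @param slice Axial (k) slice index; defaults to the middle slice.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.connectivity_map <- function(object, slice = NULL, ...) {
  d <- dim(object$z)
  slice <- slice %||% ceiling(d[3] / 2)
  df <- tidy(object) |> dplyr::filter(.data$k == slice)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$z)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("Fisher z map, slice k = %d", slice),
                  subtitle = sprintf("%s (%s)", object$subject_id, object$drug),
                  x = "i", y = "j", fill = "z") +
    ggplot2::theme_minimal()
}

#' Plot an axial slice of a statistic map
#'
#' @param object A `stat_map`.
#' @param slice Axial (k) slice index; defaults to the middle slice.
#' @param ... Unused.
#' @return A ggplot object.
#' @exportS3Method ggplot2::autoplot
autoplot.stat_map <- function(object, slice = NULL, ...) {
  d <- dim(object$stat)
  slice <- slice %||% ceiling(d[3] / 2)
  df <- tidy(object) |> dplyr::filter(.data$k == slice)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$i, y = .data$j, fill = .data$stat)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_gradient2(low = "steelblue", mid = "white",
                                  high = "firebrick", midpoint = 0) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("%s, slice k = %d", object$contrast, slice),
                  x = "i", y = "j", fill = "t") +
    ggplot2::theme_minimal()
}

#' Cell-mean connectivity plot (inverted-U display)
#'
#' Mean Fisher z per drug-by-span cell with standard-error bars, the
#' standard display of the inverted-U interaction.
#'
#' @param cells Output of [cell_means()].
#' @return A ggplot object.
#' @export
plot_cell_means <- function(cells) {
  cells <- cells |>
    tidyr::separate_wider_delim("cell", "_", names = c("span", "drug")) |>
    dplyr::mutate(drug = factor(.data$drug, levels = c("placebo", "drug")),
                  span = factor(.data$span, levels = c("low", "high")))
  ggplot2::ggplot(cells, ggplot2::aes(x = .data$span, y = .data$mean_z,
                                      fill = .data$drug)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(ggplot2::aes(ymin = .data$mean_z - .data$se,
                                        ymax = .data$mean_z + .data$se),
                           position = ggplot2::position_dodge(0.8), width = 0.2) +
    ggplot2::labs(x = "working-memory span group",
                  y = "mean midbrain-caudate Fisher z",
                  fill = "condition") +
    ggplot2::theme_minimal()
}

#' Span-connectivity scatter per condition
#'
#' Per-subject mean Fisher z against span score, one panel per condition,
#' with least-squares fits; visualises the sign flip of the
#' span-connectivity correlation between placebo and drug.
#'
#' @param values Output of [mean_z_by_subject()] (both conditions).
#' @return A ggplot object.
#' @export
plot_span_scatter <- function(values) {
  ggplot2::ggplot(values, ggplot2::aes(x = .data$span_score, y = .data$mean_z)) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         color = "grey40") +
    ggplot2::facet_wrap(~drug) +
    ggplot2::labs(x = "listening span score",
                  y = "mean midbrain-caudate Fisher z") +
    ggplot2::theme_minimal()
}
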