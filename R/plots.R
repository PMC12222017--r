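#' Heatmap of an NBLAST score matrix
#'
#' @param object An `nblast_scores` matrix.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.nblast_scores <- function(object, ...) {
  df <- tidy(object)
  ggplot2::ggplot(df, ggplot2::aes(.data$target, .data$query,
                                   fill = .data$score)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::labs(x = NULL, y = NULL, fill = "NBLAST") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 90,
                                                       vjust = 0.5))
}

#' Scatter of morphology vs connectivity scores for matched neurons
#'
#' @param object A `match_result`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.match_result <- function(object, ...) {
  m <- object[object$status == "matched", ]
  ggplot2::ggplot(m, ggplot2::aes(.data$morph_score, .data$conn_score,
                                  colour = factor(.data$confidence))) +
    ggplot2::geom_point(alpha = 0.7) +
    ggplot2::labs(x = "mean-normalized NBLAST", y = "cosine similarity",
                  colour = "confidence") +
    ggplot2::theme_minimal()
}

#' Maximum-intensity projection of a synapse density grid
#'
#' Projects the voxel counts along z and plots the x-y density map.
#'
#' @param object A `density_grid`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.density_grid <- function(object, ...) {
  df <- tidy(object) |>
    dplyr::group_by(.data$x, .data$y) |>
    dplyr::summarise(count = max(.data$count), .groups = "drop")
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$count)) +
    ggplot2::geom_tile(width = object$voxel, height = object$voxel) +
    ggplot2::scale_fill_viridis_c(trans = "sqrt") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)", fill = "synapses") +
    ggplot2::theme_minimal()
}

#' Heatmap of type-level sensory ranks
#'
#' @param type_ranks Tibble from [average_rank_by_type()].
#' @param clusters Optional tibble from [cluster_by_rank()] used to order
#'   the rows.
#' @return A ggplot object.
#' @export
plot_rank_heatmap <- function(type_ranks, clusters = NULL) {
  df <- tidyr::pivot_longer(type_ranks, -1L, names_to = "modality",
                            values_to = "rank")
  if (!is.null(clusters)) {
    ord <- clusters$type_label[order(clusters$cluster)]
    df$type_label <- factor(df$type_label, levels = ord)
  }
  ggplot2::ggplot(df, ggplot2::aes(.data$modality, .data$type_label,
                                   fill = .data$rank)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(direction = -1) +
    ggplot2::labs(x = NULL, y = NULL, fill = "rank") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.y = ggplot2::element_text(size = 5))
}

#' Paired-weight stereotypy scatter
#'
#' Plots matched connection weights from two measurements (hemispheres or
#' datasets) with the through-origin best-fit line and annotates Pearson r
#' and slope.
#'
#' @param weights_a,weights_b Paired weight vectors.
#' @param lab_a,lab_b Axis labels.
#' @return A ggplot object.
#' @export
plot_stereotypy <- function(weights_a, weights_b,
                            lab_a = "side A", lab_b = "side B") {
  st <- stereotypy_stats(weights_a, weights_b)
  df <- tibble::tibble(a = weights_a, b = weights_b)
  ggplot2::ggplot(df, ggplot2::aes(.data$a, .data$b)) +
    ggplot2::geom_point(alpha = 0.6) +
    ggplot2::geom_abline(slope = st$slope, intercept = 0,
                         linetype = "dashed") +
    ggplot2::labs(
      x = lab_a, y = lab_b,
      subtitle = sprintf("r = %.2f, slope = %.2f", st$pearson_r, st$slope)
    ) +
    ggplot2::theme_minimal()
}

#' Partner class composition bar chart
#'
#' @param composition Tibble from [class_composition()] (optionally with a
#'   `direction` column for faceting).
#' @return A ggplot object.
#' @export
plot_class_composition <- function(composition) {
  p <- ggplot2::ggplot(composition,
                       ggplot2::aes(x = "", y = .data$fraction,
                                    fill = .data$neuron_class)) +
    ggplot2::geom_col(width = 1) +
    ggplot2::coord_polar(theta = "y") +
    ggplot2::labs(x = NULL, y = NULL, fill = "class") +
    ggplot2::theme_void()
  if ("direction" %in% names(composition)) {
    p <- p + ggplot2::facet_wrap(~direction)
  }
  p
}
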