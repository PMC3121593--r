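# ggplot2 views of the main result types.

#' @export
autoplot.growth_curve <- function(object, ...) {
  long <- tidyr::pivot_longer(tibble::as_tibble(object),
                              cols = -"time_min",
                              names_to = "series", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$time_min, .data$value,
                                     colour = .data$series)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::facet_wrap(~series, scales = "free_y", ncol = 1) +
    ggplot2::labs(x = "time (min)", y = NULL,
                  title = "Diauxic growth curve") +
    ggplot2::theme_minimal() +
    ggplot2::theme(legend.position = "none")
}

#' @export
autoplot.rt_warp <- function(object, ...) {
  ggplot2::ggplot(object$anchor_pairs,
                  ggplot2::aes(.data$rt_run, .data$rt_master)) +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = "dashed",
                         colour = "grey60") +
    ggplot2::geom_point(alpha = 0.3, size = 0.7) +
    ggplot2::geom_line(data = object$knots,
                       ggplot2::aes(.data$x, .data$y), colour = "red") +
    ggplot2::labs(x = "run RT (min)", y = "master RT (min)",
                  title = sprintf("RT warp (%d anchors, residual sd %.3f min)",
                                  object$n_anchors_used,
                                  object$fit_residual_sd)) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.profile_clusters <- function(object, ...) {
  ggplot2::ggplot(object$medoids,
                  ggplot2::aes(.data$time_min, .data$value,
                               colour = .data$class)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.7) +
    ggplot2::scale_colour_manual(
      values = c(up = "#00AA00", down = "#CC0000", flat = "grey50")) +
    ggplot2::labs(x = "time relative to onset (min)", y = "log2 ratio",
                  title = "Cluster medoid profiles") +
    ggplot2::theme_minimal()
}

#' Plot one protein's expression profile
#'
#' @param matrix A `protein_matrix` (any stage).
#' @param protein_id Protein to plot.
#' @return A ggplot.
#' @export
plot_protein_profile <- function(matrix, protein_id) {
  d <- tibble::as_tibble(matrix) |>
    dplyr::filter(.data$protein_id == !!protein_id, !is.na(.data$value))
  if (nrow(d) == 0) abort(sprintf("no data for protein '%s'", protein_id))
  ylab <- switch(matrix_stage(matrix) %||% "raw",
                 raw = "summed intensity",
                 normalized = "relative intensity",
                 log2 = "log2 ratio")
  ggplot2::ggplot(d, ggplot2::aes(.data$time_min, .data$value,
                                  colour = factor(.data$replicate))) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.9) +
    ggplot2::labs(x = "time (min)", y = ylab, colour = "replicate",
                  title = protein_id) +
    ggplot2::theme_minimal()
}
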