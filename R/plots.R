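matrix_to_df <- function(m, value_name = "value") {
  tibble::tibble(row = rep(seq_len(nrow(m)), times = ncol(m)),
                 col = rep(seq_len(ncol(m)), each = nrow(m)),
                 !!value_name := as.vector(m))
}

#' Plot an uncertainty map
#'
#' Raster display of a U-map with the color scale fixed to the analytic
#' `[0, 0.5]` range, so maps of different solutions are directly
#' comparable.
#'
#' @param umap matrix from [compute_umap()] (or a `segmentation_solution`).
#' @return A ggplot object.
#' @export
plot_umap <- function(umap) {
  if (inherits(umap, "segmentation_solution")) umap <- umap$umap
  df <- matrix_to_df(umap, "uncertainty")
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row,
                                   fill = .data$uncertainty)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(limits = c(0, 0.5), option = "inferno") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL, fill = "U-map") +
    ggplot2::theme_minimal()
}

#' Plot one frame of a series with optional mask contours
#'
#' @param series a `perfusion_series`.
#' @param frame frame index to display.
#' @param mask optional label mask drawn as class contours.
#' @return A ggplot object.
#' @export
plot_frame <- function(series, frame = NULL, mask = NULL) {
  stopifnot(inherits(series, "perfusion_series"))
  if (is.null(frame)) frame <- which.max(apply(series$intensities, 3, mean))
  df <- matrix_to_df(series$intensities[, , frame], "intensity")
  p <- ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$intensity)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = NULL, y = NULL,
                  title = sprintf("%s, frame %d", series$series_id, frame)) +
    ggplot2::theme_minimal()
  if (!is.null(mask)) {
    md <- matrix_to_df(mask, "label")
    for (cls in c(1, 2))
      if (any(md$label == cls))
        p <- p + ggplot2::geom_contour(
          data = dplyr::mutate(md, z = as.numeric(.data$label == cls)),
          ggplot2::aes(z = .data$z),
          breaks = 0.5, colour = if (cls == 1) "#e41a1c" else "#377eb8",
          linewidth = 0.4)
  }
  p
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot a method comparison
#'
#' Mean myocardium Dice (± sd error bars) per dataset and selection
#' method.
#'
#' @param object a `method_comparison` from [compare_methods()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot method_comparison
#' @export
autoplot.method_comparison <- function(object, ...) {
  ggplot2::ggplot(object$summary,
                  ggplot2::aes(x = .data$dataset, y = .data$mean_dice,
                               colour = .data$method)) +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_dice - .data$sd_dice,
                   ymax = .data$mean_dice + .data$sd_dice),
      position = ggplot2::position_dodge(width = 0.3)) +
    ggplot2::labs(x = NULL, y = "myocardium Dice", colour = NULL) +
    ggplot2::theme_minimal()
}

#' Plot a motion-error sweep
#'
#' @param object a `motion_sweep` from [motion_error_sweep()].
#' @param ... unused.
#' @return A ggplot object.
#' @method autoplot motion_sweep
#' @export
autoplot.motion_sweep <- function(object, ...) {
  ggplot2::ggplot(object$per_series,
                  ggplot2::aes(x = factor(.data$level), y = .data$upp)) +
    ggplot2::geom_boxplot(outlier.size = 0.6) +
    ggplot2::labs(x = "frame displacement (px)", y = expression(U[pp])) +
    ggplot2::theme_minimal()
}

#' @importFrom rlang .data :=
NULL
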