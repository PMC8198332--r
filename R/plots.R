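#' Plot a section's per-follicle morphometry
#'
#' Lumen area against follicle area, point size by cell count, colored by
#' epithelial extension.
#'
#' @param object A `thyro_section` from [analyze_section()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.thyro_section <- function(object, ...) {
  ggplot2::ggplot(object$records,
                  ggplot2::aes(x = .data$lumen_area, y = .data$follicle_area,
                               size = .data$n_cells, color = .data$eext)) +
    ggplot2::geom_point(alpha = 0.8) +
    ggplot2::scale_color_viridis_c(name = "EExt (µm)") +
    ggplot2::labs(x = "Lumen area (µm²)",
                  y = "Follicle area (µm²)",
                  size = "Cells") +
    ggplot2::theme_minimal()
}

#' Plot fold changes of a many-to-one comparison
#'
#' Fold-change means with SD error bars per genotype and metric; significant
#' comparisons (Dunnett-adjusted) are marked.
#'
#' @param object A `thyro_comparison` from [many_to_one_compare()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.thyro_comparison <- function(object, ...) {
  d <- tidy(object)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$genotype, y = .data$fold_change_mean,
                                  fill = .data$significant)) +
    ggplot2::geom_col(width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$fold_change_mean - .data$fold_change_sd,
                   ymax = .data$fold_change_mean + .data$fold_change_sd),
      width = 0.25) +
    ggplot2::geom_hline(yintercept = 1, linetype = "dashed") +
    ggplot2::facet_wrap(~metric_name, scales = "free_y") +
    ggplot2::scale_fill_manual(values = c(`FALSE` = "grey60", `TRUE` = "#b2182b"),
                               name = sprintf("p < %.2g", object$alpha)) +
    ggplot2::labs(x = NULL, y = sprintf("Fold change over %s", object$control)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Display a lumen-area heat map with ggplot2
#'
#' @param heatmap An RGB array from [lumen_heatmap()].
#' @return A ggplot object.
#' @export
plot_lumen_heatmap <- function(heatmap) {
  rgbmat <- grDevices::rgb(heatmap[, , 1], heatmap[, , 2], heatmap[, , 3])
  dim(rgbmat) <- dim(heatmap)[1:2]
  df <- expand.grid(row = seq_len(nrow(rgbmat)), col = seq_len(ncol(rgbmat)))
  df$fill <- as.vector(rgbmat)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$col, y = .data$row)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$fill)) +
    ggplot2::scale_fill_identity() +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_fixed() +
    ggplot2::theme_void()
}

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot
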