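#' Plot a field's cells
#'
#' Scatter of cell positions coloured by phenotype or compartment - a
#' quick visual check of a sample or of the synthetic geometry.
#'
#' @param cells Cell tibble (one sample works best).
#' @param colour_by Column to colour by (default `"phenotype"`).
#' @param point_size Point size.
#' @return A ggplot.
#' @export
plot_field <- function(cells, colour_by = "phenotype", point_size = 0.6) {
  ggplot2::ggplot(cells,
                  ggplot2::aes(.data$x_um, .data$y_um,
                               colour = .data[[colour_by]])) +
    ggplot2::geom_point(size = point_size) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (µm)", y = "y (µm)", colour = colour_by) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.cohort_distance <- function(object, ...) {
  types <- object$types
  df <- as_tibble(as.data.frame.table(object$matrix,
                                      responseName = "mean_nn_um"))
  names(df)[1:2] <- c("type_a", "type_b")
  df$type_a <- factor(df$type_a, levels = types)
  df$type_b <- factor(df$type_b, levels = types)
  ggplot2::ggplot(df, ggplot2::aes(.data$type_b, .data$type_a,
                                   fill = .data$mean_nn_um)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_viridis_c(option = "magma", direction = -1,
                                  name = "mean nearest\ndistance (µm)") +
    ggplot2::labs(x = "to cell type", y = "from cell type") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.cohort_comparison <- function(object, alpha = 0.05, ...) {
  df <- as_tibble(object) %>% filter(!is.na(.data$p_adj))
  ggplot2::ggplot(df, ggplot2::aes(.data$cell_type, -log10(.data$p_adj),
                                   colour = .data$direction)) +
    ggplot2::geom_point() +
    ggplot2::geom_hline(yintercept = -log10(alpha), linetype = 2) +
    ggplot2::facet_grid(metric ~ scope, scales = "free") +
    ggplot2::labs(x = NULL, y = expression(-log[10](P[adj])),
                  colour = "higher in") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' @export
autoplot.gmm_binning <- function(object, ...) {
  df <- tibble(bin = object$bin)
  ggplot2::ggplot(df, ggplot2::aes(.data$bin)) +
    ggplot2::geom_bar() +
    ggplot2::labs(x = sprintf("%s bin (sample %s)", object$marker,
                              object$sample_id), y = "cells") +
    ggplot2::theme_minimal()
}
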