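# ggplot2 displays for each result type.

#' @exportS3Method ggplot2::autoplot
autoplot.wavelet_pyramid <- function(object, ...) {
  to_df <- function(m, lv, band) {
    r <- range(m)
    v <- if (r[1] == r[2]) m * 0 else (m - r[1]) / diff(r)
    tibble(level = lv, band = band,
           row = rep(seq_len(nrow(m)), times = ncol(m)),
           col = rep(seq_len(ncol(m)), each = nrow(m)),
           value = as.vector(v))
  }
  df <- purrr::map_dfr(intersect(c("level1", "level2"), names(object)),
                       function(lv) {
                         purrr::imap_dfr(object[[lv]], function(m, bn) {
                           to_df(m, lv, bn)
                         })
                       })
  df$band <- factor(df$band, levels = c("LL", "LH", "HL", "HH"))
  ggplot2::ggplot(df, ggplot2::aes(.data$col, -.data$row,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::facet_grid(level ~ band) +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 guide = "none") +
    ggplot2::coord_equal() +
    ggplot2::theme_void() +
    ggplot2::labs(title = "Haar wavelet sub-bands (min-max scaled)")
}

#' @exportS3Method ggplot2::autoplot
autoplot.feature_screen <- function(object, ...) {
  ggplot2::ggplot(object$anova,
                  ggplot2::aes(.data$feature, .data$f_value,
                               fill = .data$selected)) +
    ggplot2::geom_col() +
    ggplot2::facet_wrap(~level, labeller = ggplot2::label_both) +
    ggplot2::coord_flip() +
    ggplot2::labs(x = NULL, y = "one-way ANOVA F",
                  fill = paste0("P < ", object$alpha)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.mlp_fit <- function(object, ...) {
  ggplot2::ggplot(tidy(object), ggplot2::aes(.data$epoch, .data$loss)) +
    ggplot2::geom_line() +
    ggplot2::labs(title = paste("Training loss:", object$contrast),
                  y = "mean squared-error loss / sample") +
    ggplot2::theme_minimal()
}

#' Per-contrast accuracy comparison across wavelet levels
#'
#' Line graph of test accuracy per contrast, one line per wavelet level —
#' the standard way to compare level-1 against level-2 feature sets.
#'
#' @param metrics Combined metrics tibble with `level`, `contrast`,
#'   `accuracy` columns (e.g. `run$metrics` from [run_pipeline()]).
#' @return A ggplot object.
#' @export
plot_level_comparison <- function(metrics) {
  ggplot2::ggplot(metrics,
                  ggplot2::aes(.data$contrast, .data$accuracy,
                               colour = factor(.data$level),
                               group = factor(.data$level))) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::labs(x = NULL, y = "test accuracy (%)", colour = "wavelet level") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 30, hjust = 1))
}

#' Per-class feature box plots
#'
#' Box plots of each feature by grade class, optionally faceted by wavelet
#' level; the visual check that the classes separate in feature space.
#'
#' @param features Feature tibble from [extract_features()].
#' @param features_to_plot Character vector of feature columns (default all
#'   11).
#' @return A ggplot object.
#' @export
plot_feature_box <- function(features, features_to_plot = feature_names()) {
  long <- tidyr::pivot_longer(features,
                              dplyr::all_of(features_to_plot),
                              names_to = "feature")
  ggplot2::ggplot(long, ggplot2::aes(.data$label, .data$value,
                                     fill = .data$label)) +
    ggplot2::geom_boxplot(outlier.size = 0.4) +
    ggplot2::facet_grid(feature ~ level, scales = "free_y",
                        labeller = ggplot2::label_both) +
    ggplot2::labs(x = NULL, y = NULL) +
    ggplot2::guides(fill = "none") +
    ggplot2::theme_minimal()
}

#' Per-channel colour histogram plot
#'
#' @param image Integer RGB array.
#' @return A ggplot object with one curve per channel.
#' @export
plot_colour_histogram <- function(image) {
  df <- colour_histogram(image)
  ggplot2::ggplot(df, ggplot2::aes(.data$bin, .data$count,
                                   colour = .data$channel)) +
    ggplot2::geom_line() +
    ggplot2::scale_colour_manual(values = c(R = "red3", G = "green4",
                                            B = "blue3")) +
    ggplot2::labs(x = "intensity bin", y = "pixel count") +
    ggplot2::theme_minimal()
}
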