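# ggplot2 views of the main result types.

#' Mean spectrum per outcome group
#'
#' @param data A spectra table on a shared grid.
#' @return A ggplot object.
#' @export
plot_group_spectra <- function(data) {
  check_dataset(data)
  X <- spectra_matrix(data)
  w <- attr(X, "wavenumber")
  means <- purrr::map_dfr(split(seq_len(nrow(X)), data$group), function(i) {
    tibble(wavenumber = w, intensity = colMeans(X[i, , drop = FALSE]))
  }, .id = "group")
  ggplot2::ggplot(means, ggplot2::aes(.data$wavenumber, .data$intensity,
                                      colour = .data$group)) +
    ggplot2::geom_line(linewidth = 0.4) +
    ggplot2::labs(x = "Raman shift (cm-1)", y = "intensity (a.u.)",
                  colour = "group") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.peak_stats <- function(object, ...) {
  long <- tidyr::pivot_longer(object,
                              cols = c("mean_A", "mean_B", "mean_C"),
                              names_to = "group", names_prefix = "mean_",
                              values_to = "mean")
  ggplot2::ggplot(long, ggplot2::aes(factor(.data$position), .data$mean,
                                     fill = .data$group)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::geom_text(data = object,
                       ggplot2::aes(factor(.data$position),
                                    y = pmax(.data$mean_A, .data$mean_B, .data$mean_C),
                                    label = .data$pattern),
                       inherit.aes = FALSE, angle = 90, hjust = -0.1, size = 2.5) +
    ggplot2::labs(x = "core peak (cm-1)", y = "mean intensity",
                  fill = "group") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 60, hjust = 1))
}

#' @export
autoplot.raman_embedding <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$x, .data$y, colour = .data$label)) +
    ggplot2::geom_point(alpha = 0.7, size = 1) +
    ggplot2::labs(title = attr(object, "method"), colour = "group") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.model_report <- function(object, ...) {
  long <- tidyr::pivot_longer(tidy(object),
                              cols = c("sensitivity", "specificity", "auc"),
                              names_to = "metric", values_to = "value")
  ggplot2::ggplot(long, ggplot2::aes(.data$class, .data$value,
                                     fill = .data$metric)) +
    ggplot2::geom_col(position = "dodge") +
    ggplot2::coord_cartesian(ylim = c(0, 1)) +
    ggplot2::labs(title = sprintf("%s (accuracy %.2f)", object$model,
                                  object$accuracy),
                  x = "class", y = NULL, fill = NULL) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.sample_decisions <- function(object, ...) {
  dist <- sample_accuracy_distribution(object)
  h <- dist$histogram
  h$bin <- sprintf("%d-%d%%", h$bin_lo * 100, h$bin_hi * 100)
  ggplot2::ggplot(h, ggplot2::aes(factor(.data$bin, levels = .data$bin),
                                  .data$count)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = "spectra predicted correctly per sample",
                  y = "samples",
                  title = sprintf("%.0f%% of samples above 50%% correct",
                                  100 * dist$share_over_half)) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}
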