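# ggplot2 displays for each result type.

#' Plot per-layer densities
#'
#' Per-animal points with the layer mean +/- SEM, on a log10 y axis when the
#' densities span orders of magnitude (as laminar fiber densities do).
#'
#' @param records Density tibble (`animal`, `layer`, `density`).
#' @param log_y Use a log10 y scale (default `TRUE`).
#' @return A ggplot object.
#' @export
plot_layer_densities <- function(records, log_y = TRUE) {
  p <- ggplot2::ggplot(records,
                       ggplot2::aes(x = .data$layer, y = .data$density)) +
    ggplot2::stat_summary(fun = mean, geom = "col", fill = "grey80",
                          width = 0.6) +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se, geom = "errorbar",
                          width = 0.2) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$animal), size = 2) +
    ggplot2::labs(x = NULL, y = expression("signal density (" * mu * m^2 /
                                             100 ~ mu * m^2 * ")")) +
    ggplot2::theme_classic()
  if (log_y) p <- p + ggplot2::scale_y_log10()
  p
}

#' @method autoplot layer_comparison
#' @export
autoplot.layer_comparison <- function(object, ...) {
  plot_layer_densities(object$fit$model |>
                         dplyr::rename(density = 1, layer = 2) |>
                         dplyr::mutate(animal = "animal"), ...)
}

#' @method autoplot shift_corr
#' @export
autoplot.shift_corr <- function(object, ...) {
  pk <- curve_peak(object)
  ggplot2::ggplot(object, ggplot2::aes(x = .data$dx, y = .data$r)) +
    ggplot2::geom_line() +
    ggplot2::geom_vline(xintercept = 0, linetype = "dotted") +
    ggplot2::annotate("point", x = pk$peak_dx, y = pk$peak_r, colour = "red") +
    ggplot2::labs(x = "image displacement dx (px)",
                  y = "Pearson's correlation coefficient") +
    ggplot2::theme_classic()
}

#' Plot test and rotated-control shift-correlation curves
#'
#' Mean +/- SEM across samples, test pairing against the rotated null.
#'
#' @param curves Long tibble (`sample`, `dx`, `r_test`, `r_control`), as
#'   produced by [run_coloc()].
#' @return A ggplot object.
#' @export
plot_shift_curves <- function(curves) {
  long <- tidyr::pivot_longer(curves, c("r_test", "r_control"),
                              names_to = "pairing", values_to = "r",
                              names_prefix = "r_")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$dx, y = .data$r,
                                     colour = .data$pairing)) +
    ggplot2::stat_summary(fun = mean, geom = "line") +
    ggplot2::stat_summary(fun.data = ggplot2::mean_se, geom = "ribbon",
                          ggplot2::aes(fill = .data$pairing), alpha = 0.2,
                          colour = NA) +
    ggplot2::scale_colour_manual(values = c(test = "black", control = "grey60"),
                                 aesthetics = c("colour", "fill")) +
    ggplot2::labs(x = "image displacement dx (px)",
                  y = "Pearson's correlation coefficient") +
    ggplot2::theme_classic()
}

#' @method autoplot composition_cor
#' @export
autoplot.composition_cor <- function(object, ...) {
  dat <- dplyr::bind_cols(object$data,
                          abundance_color(object$data$abundance)["hex"])
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$infection, y = .data$abundance)) +
    ggplot2::geom_smooth(method = "lm", formula = y ~ x, se = FALSE,
                         colour = "grey70", linewidth = 0.5) +
    ggplot2::geom_point(ggplot2::aes(fill = .data$hex), shape = 21, size = 3) +
    ggplot2::scale_fill_identity() +
    ggplot2::labs(
      x = expression(log[10] ~ "infection ratio (MRN / DRN)"),
      y = expression(log[10] ~ "abundance ratio (GL / GCL)"),
      subtitle = sprintf("r = %.2f, p = %.3g, n = %d", object$r,
                         object$p_value, object$n)) +
    ggplot2::theme_classic()
}
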