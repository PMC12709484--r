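#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' @exportS3Method ggplot2::autoplot
autoplot.fractal_trajectory <- function(object, statistic = c("mean", "std"),
                                        ...) {
  statistic <- match.arg(statistic)
  col <- grep(paste0("^", statistic, "_"), names(object), value = TRUE)[1]
  lab <- if (statistic == "mean") "MeanDf" else "STDDf"
  trajectory_plot(object, col, lab)
}

#' @exportS3Method ggplot2::autoplot
autoplot.transform_trajectory <- function(object,
                                          statistic = c("mean", "std"),
                                          ...) {
  statistic <- match.arg(statistic)
  col <- grep(paste0("^", statistic, "_"), names(object), value = TRUE)[1]
  lab <- if (statistic == "mean") "Mean(lnDtf)" else "STD(lnDtf)"
  trajectory_plot(object, col, lab)
}

trajectory_plot <- function(object, col, lab) {
  label <- attr(object, "group_label") %||% "group"
  dat <- dplyr::mutate(tibble::as_tibble(object), group = label)
  ggplot2::ggplot(dat,
                  ggplot2::aes(x = .data$percent, y = .data[[col]],
                               colour = .data$group)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_point(na.rm = TRUE) +
    ggplot2::labs(x = "threshold (% of full scale)", y = lab,
                  colour = NULL) +
    ggplot2::theme_minimal()
}

#' Overlay two trajectories (control vs disease) with the optimum marked
#'
#' @param control,disease Trajectories over a common grid.
#' @param statistic `"mean"` or `"std"`.
#' @return A ggplot.
#' @export
plot_contrast <- function(control, disease, statistic = c("mean", "std")) {
  statistic <- match.arg(statistic)
  col <- grep(paste0("^", statistic, "_"), names(control), value = TRUE)[1]
  opt <- optimal_threshold(control, disease, statistic)
  dat <- dplyr::bind_rows(
    control = tibble::as_tibble(control),
    disease = tibble::as_tibble(disease),
    .id = "group"
  )
  ggplot2::ggplot(dat,
                  ggplot2::aes(x = .data$percent, y = .data[[col]],
                               colour = .data$group)) +
    ggplot2::geom_line(na.rm = TRUE) +
    ggplot2::geom_vline(xintercept = opt$percent, linetype = "dashed") +
    ggplot2::labs(x = "threshold (% of full scale)", y = col,
                  subtitle = sprintf("optimal threshold %.2f%% (|diff| = %.4g)",
                                     opt$percent, opt$abs_diff)) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.mf_spectrum <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$alpha, y = .data$f_alpha)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::labs(x = expression(alpha), y = expression(f(alpha))) +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.ipr_scan <- function(object, ...) {
  g <- glance(object)
  ggplot2::ggplot(g, ggplot2::aes(x = .data$l, y = .data$mean_ipr)) +
    ggplot2::geom_line() +
    ggplot2::geom_pointrange(
      ggplot2::aes(ymin = .data$mean_ipr - .data$std_ipr,
                   ymax = .data$mean_ipr + .data$std_ipr)) +
    ggplot2::scale_x_continuous(trans = "log2") +
    ggplot2::labs(x = "IPR pixel size L", y = "mean IPR") +
    ggplot2::theme_minimal()
}

#' @exportS3Method ggplot2::autoplot
autoplot.df_distribution <- function(object, ...) {
  xlab <- if (object$log_scale) "ln Df" else "Df"
  ggplot2::ggplot(object$histogram,
                  ggplot2::aes(x = .data$mid, y = .data$density)) +
    ggplot2::geom_col(width = diff(range(object$histogram$mid)) /
                        max(1, nrow(object$histogram) - 1) * 0.9) +
    ggplot2::labs(x = xlab, y = "density") +
    ggplot2::theme_minimal()
}

#' Heatmap of a per-window IPR colormap
#'
#' @param scan An [ipr_scan()] result.
#' @param image,l Which image and window size to draw.
#' @return A ggplot.
#' @export
plot_ipr_map <- function(scan, image = 1, l = max(scan$l)) {
  m <- ipr_map(scan, image, l)
  dat <- tibble::tibble(
    row = as.vector(row(m)), col = as.vector(col(m)), ipr = as.vector(m)
  )
  ggplot2::ggplot(dat, ggplot2::aes(x = .data$col, y = -.data$row,
                                    fill = .data$ipr)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = NULL, y = NULL, fill = "IPR") +
    ggplot2::theme_void()
}
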