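# ggplot2 presentation of the main result types.

#' @export
autoplot.area_profile <- function(object, ...) {
  df <- object[!object$missing, , drop = FALSE]
  ggplot2::ggplot(df, ggplot2::aes(x = .data$station_label_mm, y = .data$area_mm2)) +
    ggplot2::geom_line(colour = "grey40") +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_x_reverse(breaks = object$station_label_mm) +
    ggplot2::labs(
      x = "station (mm, + rostral of hard palate edge)",
      y = expression("cross-sectional area (mm"^2 * ")"),
      title = "Perpendicular cross-sectional area profile"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.breath_trace <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("time_s", "flow_ml_s", "volume_ml")],
    cols = c("flow_ml_s", "volume_ml"),
    names_to = "channel", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$time_s, y = .data$value)) +
    ggplot2::geom_line(linewidth = 0.3) +
    ggplot2::facet_wrap(~channel, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(flow_ml_s = "flow (ml/s)", volume_ml = "volume (ml)"))) +
    ggplot2::labs(x = "time (s)", y = NULL, title = "Plethysmography trace") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.flow_1d <- function(object, ...) {
  df <- tidyr::pivot_longer(
    tibble::as_tibble(object)[, c("s_mm", "velocity_m_s", "pressure_pa")],
    cols = c("velocity_m_s", "pressure_pa"),
    names_to = "field", values_to = "value"
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$s_mm, y = .data$value)) +
    ggplot2::geom_line() +
    ggplot2::facet_wrap(~field, ncol = 1, scales = "free_y",
                        labeller = ggplot2::as_labeller(
                          c(velocity_m_s = "mean speed (m/s)",
                            pressure_pa = "pressure (Pa)"))) +
    ggplot2::labs(x = "arclength from nostrils (mm)", y = NULL,
                  title = "Quasi-1D airflow solution") +
    ggplot2::theme_minimal()
}

#' @export
autoplot.flow_3d <- function(object, ...) {
  sp <- object$speed_m_s
  d <- dim(sp)
  j <- round(d[2] / 2)
  sl <- sp[, j, ]
  df <- tibble::tibble(
    x = rep(seq_len(d[1]), times = d[3]),
    z = rep(seq_len(d[3]), each = d[1]),
    speed = as.vector(sl)
  )
  ggplot2::ggplot(df, ggplot2::aes(x = .data$z, y = .data$x, fill = .data$speed)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = "speed (m/s)") +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "axial voxel", y = "transverse voxel",
                  title = "Midplane speed field") +
    ggplot2::theme_minimal()
}

#' Group-comparison plot for a cohort report
#'
#' Mean and SD per group for each measure of a [cohort_compare()] (or
#' [comparison_report()]) table, with significant measures highlighted.
#'
#' @param report tibble with `measure`/`metric`, `mean1`, `sd1`, `mean2`,
#'   `sd2` and `significant` columns.
#' @return a ggplot object.
#' @export
plot_comparison <- function(report) {
  key <- if ("measure" %in% names(report)) "measure" else "metric"
  df <- tidyr::pivot_longer(
    report,
    cols = c("mean1", "mean2"), names_to = "group", values_to = "mean"
  )
  df$sd <- ifelse(df$group == "mean1", report$sd1[match(df[[key]], report[[key]])],
                  report$sd2[match(df[[key]], report[[key]])])
  df$group <- ifelse(df$group == "mean1", "group 1", "group 2")
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[key]], y = .data$mean,
                                   fill = .data$group)) +
    ggplot2::geom_col(position = ggplot2::position_dodge(0.8), width = 0.7) +
    ggplot2::geom_errorbar(
      ggplot2::aes(ymin = .data$mean - .data$sd, ymax = .data$mean + .data$sd),
      position = ggplot2::position_dodge(0.8), width = 0.25
    ) +
    ggplot2::labs(x = NULL, y = "mean +/- SD",
                  title = "Two-group comparison") +
    ggplot2::theme_minimal()
}
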