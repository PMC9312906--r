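#' Plot the ablation-time-versus-power curve
#'
#' @param sweep data.frame from [power_sweep()], optionally with a `tumor`
#'   column to compare phantoms.
#' @return a ggplot object.
#' @export
plot_ablation_curve <- function(sweep) {
  sw <- sweep[sweep$achieved, , drop = FALSE]
  p <- if ("tumor" %in% names(sw)) {
    ggplot2::ggplot(sw, ggplot2::aes(x = .data$power, y = .data$t_abl,
                                     colour = .data$tumor))
  } else {
    ggplot2::ggplot(sw, ggplot2::aes(x = .data$power, y = .data$t_abl))
  }
  p + ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = "input power (W)", y = "ablation time (s)")
}

#' Plot the heating-centre temperature history
#'
#' @param run an `mwa_run` (or a data.frame with `time` and `T_monitor`).
#' @return a ggplot object.
#' @export
plot_temperature_series <- function(run) {
  ser <- if (inherits(run, "mwa_run")) run$series else run
  ggplot2::ggplot(ser, ggplot2::aes(x = .data$time, y = .data$T_monitor)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "temperature (°C)")
}

#' Plot a cut plane of a simulated field
#'
#' @param grid an `mwa_grid`.
#' @param field 3D array (e.g. `state$T` or damage fraction).
#' @param axis,at passed to [cut_plane()].
#' @param label fill legend label.
#' @return a ggplot object.
#' @export
plot_cut_plane <- function(grid, field, axis = 1, at = NULL, label = "value") {
  df <- cut_plane(grid, field, axis = axis, at = at)
  nms <- names(df)
  ggplot2::ggplot(df, ggplot2::aes(x = .data[[nms[1]]] * 1e3,
                                   y = .data[[nms[2]]] * 1e3,
                                   fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_fill_viridis_c(name = label) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = paste(nms[1], "(mm)"), y = paste(nms[2], "(mm)"))
}
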