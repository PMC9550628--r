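# ggplot2 visualisation helpers for the main result types.

#' Plot a transform accuracy map
#'
#' Per-point transformation error across the field of view; a spatially
#' uncorrelated error map indicates a well-conditioned calibration.
#'
#' @param object An [accuracy_report()].
#' @param ... Unused.
#' @method autoplot accuracy_report
#' @export
autoplot.accuracy_report <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$x_wf, y = .data$y_wf,
                               colour = .data$error_nm)) +
    ggplot2::geom_point(size = 2) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (widefield px)", y = "y (widefield px)",
                  colour = "error (nm)",
                  title = sprintf("Mean transformation error %.1f nm",
                                  attr(object, "mean_error_nm")))
}

#' Plot a dF/F0 intensity trace
#'
#' @param object An intensity trace from [dff0_trace()].
#' @param ... Unused.
#' @method autoplot intensity_trace
#' @export
autoplot.intensity_trace <- function(object, ...) {
  ggplot2::ggplot(as_tibble(object),
                  ggplot2::aes(x = .data$t_s, y = .data$dff0)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (s)", y = "dF/F0")
}

#' Overlay detected events on a widefield frame
#'
#' @param frame Numeric matrix (one widefield frame).
#' @param events Event tibble (`x`, `y`, `salience`).
#' @export
plot_events <- function(frame, events) {
  df <- tidyr::expand_grid(y = seq_len(nrow(frame)) - 1L,
                           x = seq_len(ncol(frame)) - 1L)
  df$value <- as.numeric(t(frame))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_raster(ggplot2::aes(fill = .data$value)) +
    ggplot2::scale_fill_gradient(low = "black", high = "white") +
    ggplot2::geom_point(data = events,
                        ggplot2::aes(x = .data$x, y = .data$y),
                        colour = "green", shape = 0, size = 4) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(fill = "counts")
}

#' Plot linked tracks or cluster traces
#'
#' @param tracks Tibble from [link_tracks()] or [link_cluster_traces()].
#' @export
plot_tracks <- function(tracks) {
  idcol <- if ("track" %in% names(tracks)) "track" else "trace"
  ggplot2::ggplot(tracks,
                  ggplot2::aes(x = .data$x, y = .data$y,
                               group = .data[[idcol]],
                               colour = factor(.data[[idcol]]))) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::coord_equal() +
    ggplot2::labs(colour = idcol)
}

#' Plot an MSD curve
#'
#' @param msd Tibble from [compute_msd()] or [msd_ensemble()].
#' @param dt_s Frame interval in seconds (optional; x axis in frames if
#'   omitted).
#' @export
plot_msd <- function(msd, dt_s = NULL) {
  df <- msd
  df$dt <- if (is.null(dt_s)) df$dt_frames else df$dt_frames * dt_s
  ggplot2::ggplot(df, ggplot2::aes(x = .data$dt, y = .data$msd)) +
    ggplot2::geom_line() + ggplot2::geom_point() +
    ggplot2::labs(x = if (is.null(dt_s)) expression(Delta * t ~ "(frames)")
                  else expression(Delta * t ~ "(s)"),
                  y = if (identical(df$mode[1L], "squared"))
                    expression(MSD ~ (mu * m^2)) else expression(MSD ~ (mu * m)))
}
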