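# visualization: autoplot methods and depth-/time-coded MIP export

mat_to_df <- function(m) {
  tibble(x = as.vector(col(m)), y = as.vector(row(m)), value = as.vector(m))
}

#' @export
autoplot.ts_frame <- function(object, ...) {
  df <- mat_to_df(unclass(object))
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient(low = "black", high = "white",
                                 limits = c(0, 255)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = sprintf("time surface, t = %g ms",
                                  attr(object, "t_frame_ms")),
                  fill = "value")
}

#' @export
autoplot.refocused_volume <- function(object, ...) {
  mip <- apply(unclass(object), c(1, 2), max)
  df <- mat_to_df(mip)
  ggplot2::ggplot(df, ggplot2::aes(.data$x, .data$y, fill = .data$value)) +
    ggplot2::geom_raster() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(title = "maximum intensity projection", fill = "intensity")
}

#' @export
autoplot.trace <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(.data$time_ms, .data$value)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "time (ms)", y = "mean ROI intensity")
}

#' @export
autoplot.track_set <- function(object, ...) {
  ggplot2::ggplot(object,
                  ggplot2::aes(.data$x_um, .data$y_um, colour = .data$z_um,
                               group = .data$id)) +
    ggplot2::geom_path() +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_colour_viridis_c() +
    ggplot2::coord_fixed() +
    ggplot2::labs(x = "x (um)", y = "y (um)", colour = "z (um)")
}

#' @export
autoplot.xcorr_matrix <- function(object, ...) {
  m <- unclass(object)
  df <- tibble(trace = as.vector(row(m)), stimulus = as.vector(col(m)),
               r = as.vector(m))
  ggplot2::ggplot(df, ggplot2::aes(.data$stimulus, .data$trace,
                                   fill = .data$r)) +
    ggplot2::geom_tile() +
    ggplot2::scale_y_reverse() +
    ggplot2::scale_fill_gradient2(limits = c(-1, 1)) +
    ggplot2::coord_fixed() +
    ggplot2::labs(fill = "r")
}

#' @export
autoplot.spike_summary <- function(object, ...) {
  w <- object$waveform
  ggplot2::ggplot(w, ggplot2::aes(.data$time_ms, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$stderr,
                                      ymax = .data$mean + .data$stderr),
                         alpha = 0.3) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "peri-onset time (ms)", y = "mean intensity")
}

#' Depth color-coded maximum intensity projection
#'
#' Colormap convention: hue encodes the depth of the brightest voxel along z
#' (blue = shallowest plane through red = deepest), value encodes the MIP
#' intensity normalized to the volume maximum, saturation is 1.
#'
#' @param volume a `refocused_volume`
#' @return array `[y, x, 3]` of RGB values in `[0, 1]`
#' @export
depth_coded_mip <- function(volume) {
  v <- unclass(volume)
  mip <- apply(v, c(1, 2), max)
  arg <- apply(v, c(1, 2), which.max)
  nz <- dim(v)[3]
  hue <- 0.7 * (1 - (arg - 1) / max(1, nz - 1))   # blue -> red
  val <- mip / max(mip, 1e-12)
  cols <- grDevices::hsv(pmin(pmax(hue, 0), 1), 1, pmin(val, 1))
  rgb <- grDevices::col2rgb(cols) / 255
  array(c(rgb[1, ], rgb[2, ], rgb[3, ]), c(nrow(mip), ncol(mip), 3))
}

#' Write a depth-coded MIP as an RGB PNG
#'
#' @param volume a `refocused_volume`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_mip_png <- function(volume, path) {
  png::writePNG(depth_coded_mip(volume), path)
  invisible(path)
}
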