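# event2frame: polarity-sorted exponential time surfaces at a user-defined
# accumulation window, with median denoising

new_ts_frame <- function(mat, t_frame_ms, delta_ms, tau_ms, polarity_mode) {
  structure(mat, t_frame_ms = t_frame_ms, delta_ms = delta_ms, tau_ms = tau_ms,
            polarity_mode = polarity_mode, class = "ts_frame")
}

#' @export
print.ts_frame <- function(x, ...) {
  cat(sprintf("<ts_frame> %dx%d px at t = %g ms (window %g ms, tau %g ms, %s)\n",
              nrow(x), ncol(x), attr(x, "t_frame_ms"), attr(x, "delta_ms"),
              attr(x, "tau_ms"), attr(x, "polarity_mode")))
  invisible(x)
}

ts_surface_one <- function(stream, nr, nc, t_lo_us, t_hi_us, tau_us, pol) {
  # events are time-sorted; locate the window by binary search
  i0 <- findInterval(t_lo_us - 0.5, stream$t) + 1L
  i1 <- findInterval(t_hi_us + 0.5, stream$t)
  out <- matrix(0, nr, nc)
  if (i1 < i0) return(out)
  x <- stream$x[i0:i1]; y <- stream$y[i0:i1]; t <- stream$t[i0:i1]
  p <- stream$p[i0:i1]
  keep <- t >= t_lo_us & t <= t_hi_us & p == pol
  if (!any(keep)) return(out)
  x <- x[keep]; y <- y[keep]; t <- t[keep]
  # most recent event per pixel: last occurrence in time order
  pid <- y * nc + x
  last <- !duplicated(pid, fromLast = TRUE)
  # 1e-9 guards exact-half values against float representation error
  v <- round_half_up(255 * exp(-(t_hi_us - t[last]) / tau_us) + 1e-9)
  out[cbind(y[last] + 1L, x[last] + 1L)] <- v
  out
}

#' Exponential time surface at one frame timestamp
#'
#' For each pixel, `t_last` is the most recent event of the selected polarity
#' in `[t_frame - delta, t_frame]`; the pixel value is
#' `round(255 * exp(-(t_frame - t_last) / tau))`, or 0 with no such event.
#' `"combined"` mode takes the per-pixel maximum of the positive and negative
#' surfaces. A frame requested before the stream starts is all zeros.
#'
#' @param stream an [event_stream()]
#' @param t_frame_ms frame timestamp, ms
#' @param delta_ms accumulation window, ms
#' @param tau_ms decay constant, ms (default `delta_ms / 3`, so events at the
#'   window's far edge decay below 5% weight)
#' @param polarity_mode `"combined"`, `"positive"` or `"negative"`
#' @return a `ts_frame` (integer-valued matrix in `[0, 255]`)
#' @export
time_surface <- function(stream, t_frame_ms, delta_ms, tau_ms = delta_ms / 3,
                         polarity_mode = c("combined", "positive", "negative")) {
  polarity_mode <- match.arg(polarity_mode)
  check_scalar_pos(delta_ms, "delta_ms")
  check_scalar_pos(tau_ms, "tau_ms")
  ss <- attr(stream, "sensor_shape")
  nr <- ss[2]; nc <- ss[1]
  t_hi <- t_frame_ms * 1000; t_lo <- t_hi - delta_ms * 1000
  tau_us <- tau_ms * 1000
  mat <- switch(polarity_mode,
    positive = ts_surface_one(stream, nr, nc, t_lo, t_hi, tau_us, 1L),
    negative = ts_surface_one(stream, nr, nc, t_lo, t_hi, tau_us, -1L),
    combined = pmax(ts_surface_one(stream, nr, nc, t_lo, t_hi, tau_us, 1L),
                    ts_surface_one(stream, nr, nc, t_lo, t_hi, tau_us, -1L))
  )
  new_ts_frame(mat, t_frame_ms, delta_ms, tau_ms, polarity_mode)
}

#' Convert an event stream to a uniformly spaced frame sequence
#'
#' Frames are timestamped at the trailing edge of each accumulation window:
#' `t_start + k * delta` for `k = 1 .. floor((t_end - t_start) / delta)`. The
#' effective frame rate is `1000 / delta_ms` Hz; the choice of window is pure
#' post-processing and never alters the underlying stream.
#'
#' @inheritParams time_surface
#' @param t_start_ms,t_end_ms span to convert, ms (defaults to the stream span)
#' @return a `frame_sequence`: list with `frames`, `times_ms`, `delta_ms`,
#'   `frame_rate_hz`
#' @export
frame_sequence <- function(stream, delta_ms, t_start_ms = NULL,
                           t_end_ms = NULL, tau_ms = delta_ms / 3,
                           polarity_mode = "combined") {
  check_scalar_pos(delta_ms, "delta_ms")
  quantum_ms <- 1e-3
  if (delta_ms < quantum_ms) {
    stop_invalid("`delta_ms` below the sensor timestamp quantum")
  }
  span <- stream_span_ms(stream)
  t_start_ms <- t_start_ms %||% span[1]
  t_end_ms <- t_end_ms %||% span[2]
  if (t_end_ms < t_start_ms) stop_invalid("`t_end_ms` before `t_start_ms`")
  n <- floor((t_end_ms - t_start_ms) / delta_ms + 1e-9)
  times <- t_start_ms + seq_len(n) * delta_ms
  frames <- lapply(times, function(tf) {
    time_surface(stream, tf, delta_ms, tau_ms, polarity_mode)
  })
  structure(list(frames = frames, times_ms = times, delta_ms = delta_ms,
                 frame_rate_hz = 1000 / delta_ms, tau_ms = tau_ms,
                 polarity_mode = polarity_mode),
            class = "frame_sequence")
}

#' @export
print.frame_sequence <- function(x, ...) {
  cat(sprintf("<frame_sequence> %d frames at %g Hz (window %g ms)\n",
              length(x$frames), x$frame_rate_hz, x$delta_ms))
  invisible(x)
}

#' Median-filter a time-surface frame
#'
#' 2D median filter with replicated edges, suppressing isolated noise events;
#' the `[0, 255]` range is preserved. `kernel = 1` is the identity.
#'
#' @param frame a `ts_frame` (or plain matrix)
#' @param kernel odd kernel side length, px
#' @return filtered frame of the same class
#' @export
denoise_frame <- function(frame, kernel = 3L) {
  if (kernel %% 2 != 1 || kernel < 1) {
    stop_invalid("`kernel` must be odd and >= 1")
  }
  out <- median_filter(unclass(frame), as.integer(kernel))
  attributes(out) <- attributes(frame)
  out
}

#' Denoise every frame of a sequence
#'
#' @param fs a `frame_sequence`
#' @param kernel odd kernel side length
#' @return the sequence with filtered frames
#' @export
denoise_sequence <- function(fs, kernel = 3L) {
  fs$frames <- lapply(fs$frames, denoise_frame, kernel = kernel)
  fs
}
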