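# shared fixtures: a small 5x5 geometry and compact scenes/streams

tiny_geometry <- function(view_size = 32, ...) {
  system_geometry(grid_side = 5, view_size = view_size,
                  view_pitch = view_size, z_range = c(-10, 10),
                  lateral_um_per_px = 1, ...)
}

# a volume with a single point source at the lateral center
point_volume <- function(view_size, z, value = 1) {
  c0 <- floor(view_size / 2) + 1L
  vol <- array(0, c(view_size, view_size, 1L))
  vol[c0, c0, 1L] <- value
  attr(vol, "z_planes") <- z
  vol
}

# deterministic event stream from a data frame
stream_of <- function(df, shape = c(32, 32)) {
  event_stream(tibble::as_tibble(df), sensor_shape = shape)
}

# event stream of a laterally moving bead (used by sensor/frames tests)
moving_bead_stream <- function(speed_mm_s = 1, duration_ms = 20,
                               brightness = 100, seed = 1,
                               noise_rate = 0, latency = c(100, 220)) {
  geom <- tiny_geometry()
  scene <- make_linear_motion_phantom(
    1, extent_um = c(32, 32, 20), thickness_um = 1, speed_mm_s = speed_mm_s,
    duration_ms = duration_ms, direction = c(0, 1, 0),
    brightness = brightness, seed = seed)
  simulate_recording(scene, geom,
                     sensor_config(noise_rate = noise_rate,
                                   latency_range_us = latency),
                     0.25, seed)
}

# brute-force shift-and-sum oracle over all views (integer shifts)
refocus_oracle <- function(views, alpha, depths) {
  uv <- attr(views, "uv")
  d <- dim(views)
  out <- array(0, c(d[1], d[2], length(depths)))
  for (kz in seq_along(depths)) {
    acc <- matrix(0, d[1], d[2])
    for (a in seq_len(d[3])) for (b in seq_len(d[4])) {
      dx <- -uv[b] * alpha * depths[kz]
      dy <- -uv[a] * alpha * depths[kz]
      src <- views[, , a, b]
      dst <- matrix(0, d[1], d[2])
      for (r in seq_len(d[1])) for (c in seq_len(d[2])) {
        rr <- r - dy; cc <- c - dx
        if (rr >= 1 && rr <= d[1] && cc >= 1 && cc <= d[2]) {
          dst[r, c] <- src[rr, cc]
        }
      }
      acc <- acc + dst
    }
    out[, , kz] <- acc / (d[3] * d[4])
  }
  out
}

# intensity-weighted centroid of a matrix (row, col)
centroid_of <- function(m) {
  tot <- sum(m)
  c(sum(row(m) * m) / tot, sum(col(m) * m) / tot)
}
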