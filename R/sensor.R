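# event_sensor: contrast-threshold event generation and event-stream I/O

#' Event sensor configuration
#'
#' Parameters of the contrast-threshold ("ladder") event model: a pixel holds
#' a log-intensity reference; each time the log intensity crosses the
#' reference by +-`contrast_threshold` an event of that polarity is emitted,
#' the reference advances to the crossed level, a readout latency drawn
#' uniformly from `latency_range_us` is added, and the timestamp is quantized
#' to `timestamp_quantum_us`.
#'
#' @param contrast_threshold log-intensity step per event (~25% contrast by
#'   default; typical event-camera setting)
#' @param latency_range_us c(min, max) pixel latency, us
#' @param refractory_us pixel dead time after an event, us; `NULL` (default)
#'   uses each event's own latency sample
#' @param noise_rate spontaneous events per pixel per second (random polarity)
#' @param log_floor intensity added before taking logs, keeps log defined at
#'   zero background
#' @param timestamp_quantum_us timestamp granularity, us
#' @return an object of class `sensor_config`
#' @export
sensor_config <- function(contrast_threshold = 0.25,
                          latency_range_us = c(100, 220),
                          refractory_us = NULL, noise_rate = 0.1,
                          log_floor = 1, timestamp_quantum_us = 1) {
  check_scalar_pos(contrast_threshold, "contrast_threshold")
  if (length(latency_range_us) != 2 || latency_range_us[1] > latency_range_us[2] ||
      any(latency_range_us < 0)) {
    stop_invalid("`latency_range_us` must be c(min, max) with 0 <= min <= max")
  }
  check_scalar_pos(timestamp_quantum_us, "timestamp_quantum_us")
  if (noise_rate < 0) stop_invalid("`noise_rate` must be >= 0")
  structure(list(contrast_threshold = contrast_threshold,
                 latency_range_us = as.numeric(latency_range_us),
                 refractory_us = refractory_us, noise_rate = noise_rate,
                 log_floor = log_floor,
                 timestamp_quantum_us = timestamp_quantum_us),
            class = "sensor_config")
}

#' Event stream container
#'
#' A tibble of asynchronous events sorted by `(t, y, x, p)` with 0-based pixel
#' coordinates, integer-microsecond timestamps and polarity in `{-1, +1}`,
#' plus the sensor shape and generation metadata as attributes.
#'
#' @param events data frame with columns `x`, `y`, `t`, `p`
#' @param sensor_shape c(width, height), px
#' @param meta metadata list
#' @return a tibble of class `event_stream`
#' @export
event_stream <- function(events, sensor_shape, meta = list()) {
  events <- as_tibble(events)[, c("x", "y", "t", "p")]
  if (nrow(events)) {
    if (!all(events$p %in% c(-1, 1))) {
      stop_invalid("polarity must be -1 or +1", "evlfm_parse_error")
    }
    if (any(events$t < 0)) stop_invalid("timestamps must be >= 0")
    if (any(events$x < 0 | events$x >= sensor_shape[1] |
            events$y < 0 | events$y >= sensor_shape[2])) {
      stop_invalid("event coordinates outside the sensor",
                   "evlfm_validation_error")
    }
    events <- events[order(events$t, events$y, events$x, events$p), ]
  }
  structure(events, sensor_shape = as.integer(sensor_shape), meta = meta,
            class = c("event_stream", class(tibble())))
}

#' @export
print.event_stream <- function(x, ...) {
  ss <- attr(x, "sensor_shape")
  cat(sprintf("<event_stream> %d events on a %dx%d sensor", nrow(x), ss[1], ss[2]))
  if (nrow(x)) cat(sprintf(", t in [%d, %d] us", min(x$t), max(x$t)))
  cat("\n")
  invisible(x)
}

#' Span of an event stream in milliseconds
#' @param stream an [event_stream()]
#' @return c(start, end), ms
#' @export
stream_span_ms <- function(stream) {
  if (!nrow(stream)) return(c(0, 0))
  c(min(stream$t), max(stream$t)) / 1000
}

#' Simulate an event stream from a sequence of sensor images
#'
#' Per pixel, the log intensity `L(t) = log(I(t) + log_floor)` is tracked with
#' linear interpolation between frames. Each crossing of the reference by
#' `+-contrast_threshold` emits an event with the crossing's sign, advances
#' the reference to the crossed level, adds a latency sample and quantizes the
#' timestamp. Crossings falling inside a pixel's refractory window are
#' suppressed (the reference still advances). Independent Poisson noise events
#' are added at `noise_rate` with random polarity.
#'
#' @param frames list of sensor images (matrices `[y, x]`), a 3D array with
#'   the frame index last, or a function `f(k)` returning frame `k` (lazy
#'   rendering: frames are produced one at a time and never held together
#'   in memory)
#' @param times_ms strictly increasing frame timestamps, ms
#' @param config a [sensor_config()]
#' @param seed integer seed (latency, noise)
#' @return an [event_stream()]
#' @export
simulate_events <- function(frames, times_ms, config = sensor_config(),
                            seed = NULL) {
  if (is.array(frames) && length(dim(frames)) == 3) {
    arr <- frames
    frames <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k])
  }
  get_frame <- if (is.function(frames)) frames else function(k) frames[[k]]
  n_frames <- length(times_ms)
  if (n_frames < 2) {
    stop_invalid("at least two frames are required", "evlfm_insufficient_input")
  }
  if (!is.function(frames) && length(frames) != n_frames) {
    stop_invalid("`times_ms` must have one timestamp per frame")
  }
  if (any(diff(times_ms) <= 0)) {
    stop_invalid("`times_ms` must be strictly increasing, one per frame")
  }
  f1 <- get_frame(1L)
  nr <- nrow(f1); nc <- ncol(f1)
  C <- config$contrast_threshold
  eps <- config$log_floor
  lat <- config$latency_range_us
  times_us <- times_ms * 1000
  q <- config$timestamp_quantum_us

  with_seed_(seed, {
    L_prev <- {
      if (any(f1 < 0)) stop_invalid("negative intensities are not allowed")
      log(f1 + eps)
    }
    ref <- L_prev
    block_until <- matrix(-Inf, nr, nc)
    acc <- vector("list", n_frames - 1L)
    for (k in 2:n_frames) {
      f <- get_frame(k)
      if (any(f < 0)) stop_invalid("negative intensities are not allowed")
      L <- log(f + eps)
      dL <- L - L_prev
      up <- L > ref
      m <- matrix(0L, nr, nc)
      m[up] <- floor((L[up] - ref[up]) / C + 1e-9)
      dn <- L < ref
      m[dn] <- floor((ref[dn] - L[dn]) / C + 1e-9)
      mmax <- max(m)
      if (mmax > 0) {
        t0 <- times_us[k - 1]; dt <- times_us[k] - t0
        parts <- vector("list", mmax)
        for (j in seq_len(mmax)) {
          sel <- which(m >= j)
          if (!length(sel)) break
          pol <- ifelse(up[sel], 1L, -1L)
          level <- ref[sel] + pol * j * C
          # linear interpolation of the crossing time inside the interval
          t_ideal <- t0 + (level - L_prev[sel]) / dL[sel] * dt
          ok <- t_ideal >= block_until[sel]
          latency <- runif(length(sel), lat[1], lat[2])
          refr <- config$refractory_us %||% latency   # scalar or per-event
          refr_ok <- if (length(refr) == 1) rep(refr, sum(ok)) else refr[ok]
          block_until[sel[ok]] <- t_ideal[ok] + refr_ok
          if (any(ok)) {
            tstamp <- round_half_up((t_ideal[ok] + latency[ok]) / q) * q
            parts[[j]] <- list(
              x = ((sel[ok] - 1L) %/% nr),          # 0-based column
              y = ((sel[ok] - 1L) %% nr),           # 0-based row
              t = tstamp, p = pol[ok])
          }
        }
        # advance references past all crossings
        ref <- ref + ifelse(up, 1, -1) * m * C
        acc[[k - 1L]] <- parts
      }
      L_prev <- L
    }
    ev <- unlist(acc, recursive = FALSE)
    ev <- ev[!vapply(ev, is.null, logical(1))]
    events <- if (length(ev)) {
      tibble(x = unlist(lapply(ev, `[[`, "x")),
             y = unlist(lapply(ev, `[[`, "y")),
             t = unlist(lapply(ev, `[[`, "t")),
             p = unlist(lapply(ev, `[[`, "p")))
    } else {
      tibble(x = integer(), y = integer(), t = numeric(), p = integer())
    }
    # Poisson noise events, uniform in space and time, random polarity
    if (config$noise_rate > 0) {
      span_s <- (times_us[length(times_us)] - times_us[1]) / 1e6
      n_noise <- rpois(1, config$noise_rate * nr * nc * span_s)
      if (n_noise > 0) {
        noise <- tibble(
          x = sample.int(nc, n_noise, replace = TRUE) - 1L,
          y = sample.int(nr, n_noise, replace = TRUE) - 1L,
          t = round_half_up(runif(n_noise, times_us[1], times_us[length(times_us)]) / q) * q,
          p = sample(c(-1L, 1L), n_noise, replace = TRUE))
        events <- dplyr::bind_rows(events, noise)
      }
    }
    event_stream(events, sensor_shape = c(nc, nr),
                 meta = list(config = config, seed = seed,
                             n_frames = n_frames))
  })
}

#' Write an event stream to disk
#'
#' CSV dialect: header `x,y,t,p`, one event per line, timestamps in integer
#' microseconds.
#'
#' @param stream an [event_stream()]
#' @param path output path
#' @param format only `"csv"` is supported
#' @return `path`, invisibly
#' @export
write_events <- function(stream, path, format = "csv") {
  format <- match.arg(format, "csv")
  df <- as.data.frame(stream)[, c("x", "y", "t", "p")]
  df$t <- format(df$t, scientific = FALSE, trim = TRUE)
  tryCatch(
    write.table(df, path, sep = ",", quote = FALSE, row.names = FALSE),
    error = function(e) abort(paste0("cannot write events: ", conditionMessage(e)),
                              class = c("evlfm_io_error", "evlfm_error"))
  )
  invisible(path)
}

#' Read an event stream from disk
#'
#' Reads the CSV dialect written by [write_events()]. Records are validated
#' (`p` in `{-1, +1}`, non-negative integer-microsecond timestamps,
#' coordinates inside the sensor when a shape is supplied) and returned
#' time-sorted; ties keep their on-disk order.
#'
#' @param path input path
#' @param sensor_shape optional c(width, height) for coordinate validation;
#'   defaults to a bounding shape inferred from the data
#' @return an [event_stream()]
#' @export
read_events <- function(path, sensor_shape = NULL) {
  df <- tryCatch(read.csv(path, colClasses = "numeric"),
                 error = function(e) abort(
                   paste0("cannot parse event file: ", conditionMessage(e)),
                   class = c("evlfm_parse_error", "evlfm_error")))
  if (!all(c("x", "y", "t", "p") %in% names(df))) {
    abort("event file must have columns x,y,t,p",
          class = c("evlfm_parse_error", "evlfm_error"))
  }
  bad <- which(!(df$p %in% c(-1, 1)))
  if (length(bad)) {
    abort(sprintf("invalid polarity at data row %d", bad[1]),
          class = c("evlfm_parse_error", "evlfm_error"))
  }
  bad <- which(df$t < 0 | df$t != floor(df$t))
  if (length(bad)) {
    abort(sprintf("invalid timestamp at data row %d", bad[1]),
          class = c("evlfm_parse_error", "evlfm_error"))
  }
  sensor_shape <- sensor_shape %||% c(max(df$x) + 1, max(df$y) + 1)
  if (any(df$x < 0 | df$x >= sensor_shape[1] |
          df$y < 0 | df$y >= sensor_shape[2])) {
    abort("event coordinates outside the sensor",
          class = c("evlfm_validation_error", "evlfm_error"))
  }
  df <- df[order(df$t), ]   # stable: ties keep file order
  structure(as_tibble(df), sensor_shape = as.integer(sensor_shape),
            meta = list(source = path),
            class = c("event_stream", class(tibble())))
}

#' @export
glance.event_stream <- function(x, ...) {
  span <- stream_span_ms(x)
  tibble(n_events = nrow(x), t_start_ms = span[1], t_end_ms = span[2],
         rate_hz = if (diff(span) > 0) nrow(x) / diff(span) * 1000 else NA_real_,
         frac_positive = if (nrow(x)) mean(x$p == 1) else NA_real_)
}
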