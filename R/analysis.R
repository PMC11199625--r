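# analysis: FWHM resolution, temporal traces, stimulus cross-correlation,
# spike averaging, 3D centroid tracking, velocity estimation, training losses

#' Full width at half maximum of a 1D profile
#'
#' Width at half of (max - baseline) above the baseline (profile minimum),
#' with linear interpolation between samples. The profile must have an
#' interior maximum above the baseline.
#'
#' @param profile numeric samples
#' @param pitch um per sample
#' @return FWHM in um
#' @export
fwhm <- function(profile, pitch = 1) {
  n <- length(profile)
  if (n < 3) abort("profile too short", class = c("evlfm_no_peak", "evlfm_error"))
  base <- min(profile)
  pk <- which.max(profile)
  if (profile[pk] <= base || pk == 1L || pk == n) {
    abort("profile has no interior peak above baseline",
          class = c("evlfm_no_peak", "evlfm_error"))
  }
  half <- base + (profile[pk] - base) / 2
  # walk left and right from the peak to the first half crossing
  left <- NA_real_
  for (i in pk:2) {
    if (profile[i - 1] <= half) {
      left <- (i - 1) + (half - profile[i - 1]) / (profile[i] - profile[i - 1])
      break
    }
  }
  right <- NA_real_
  for (i in pk:(n - 1)) {
    if (profile[i + 1] <= half) {
      right <- i + (profile[i] - half) / (profile[i] - profile[i + 1])
      break
    }
  }
  if (is.na(left) || is.na(right)) {
    abort("half level never crossed on one side",
          class = c("evlfm_no_peak", "evlfm_error"))
  }
  (right - left) * pitch
}

#' Lateral and axial resolution at a bead
#'
#' Refines the peak near `seed_point`, extracts the x-profile (through the
#' peak row/plane) and the z-profile (through the peak pixel), and applies
#' [fwhm()] to each. Scale-invariant in the volume intensity.
#'
#' @param volume a `refocused_volume`
#' @param seed_point c(row, col, plane) voxel indices near a local maximum
#' @param refine_radius search radius for the peak, voxels
#' @return one-row tibble: `lateral_fwhm_um`, `axial_fwhm_um`,
#'   `peak_x_um`, `peak_y_um`, `peak_z_um`
#' @export
resolution_report <- function(volume, seed_point, refine_radius = 4L) {
  d <- dim(volume)
  sp <- as.integer(seed_point)
  rr <- pmax(1L, sp - refine_radius)
  cc <- pmin(d, sp + refine_radius)
  sub <- volume[rr[1]:cc[1], rr[2]:cc[2], rr[3]:cc[3], drop = FALSE]
  k <- which.max(sub)
  ds <- dim(sub)
  pr <- (k - 1L) %% ds[1] + rr[1]
  pc <- ((k - 1L) %/% ds[1]) %% ds[2] + rr[2]
  pz <- (k - 1L) %/% (ds[1] * ds[2]) + rr[3]
  pitch <- attr(volume, "lateral_um_per_px") %||% 1
  z_planes <- attr(volume, "z_planes")
  zp <- if (length(z_planes) > 1) mean(diff(z_planes)) else 1
  lat <- fwhm(volume[pr, , pz], pitch)
  axi <- fwhm(volume[pr, pc, ], zp)
  tibble(lateral_fwhm_um = lat, axial_fwhm_um = axi,
         peak_x_um = (pc - 0.5) * pitch, peak_y_um = (pr - 0.5) * pitch,
         peak_z_um = z_planes[pz])
}

#' Volume sequence container
#'
#' @param volumes list of `refocused_volume`s
#' @param times_ms frame timestamps, ms
#' @return a `volume_sequence`
#' @export
volume_sequence <- function(volumes, times_ms) {
  if (length(volumes) != length(times_ms)) {
    stop_invalid("one timestamp per volume required")
  }
  structure(list(volumes = volumes, times_ms = as.numeric(times_ms)),
            class = "volume_sequence")
}

#' Mean-intensity trace over a region of interest
#'
#' @param x a `frame_sequence` or `volume_sequence`
#' @param roi logical mask matching the frame/volume shape, or an index matrix
#'   as used by `[`
#' @return a `trace` tibble with columns `time_ms`, `value`
#' @export
extract_trace <- function(x, roi) {
  if (is.logical(roi) && !any(roi)) stop_invalid("`roi` is empty")
  if (!is.logical(roi) && !length(roi)) stop_invalid("`roi` is empty")
  items <- if (inherits(x, "frame_sequence")) x$frames
           else if (inherits(x, "volume_sequence")) x$volumes
           else stop_invalid("`x` must be a frame_sequence or volume_sequence")
  vals <- vapply(items, function(im) mean(unclass(im)[roi]), numeric(1))
  structure(tibble(time_ms = x$times_ms, value = vals),
            class = c("trace", class(tibble())))
}

#' Peak-to-baseline contrast of a trace
#'
#' Baseline is the `baseline_q` quantile of the trace; the ratio is capped to
#' keep zero-baseline (fully suppressed background) traces finite.
#'
#' @param trace a `trace`
#' @param baseline_q baseline quantile
#' @param cap maximum reported contrast
#' @return scalar contrast
#' @export
trace_contrast <- function(trace, baseline_q = 0.5, cap = 1000) {
  v <- trace$value
  pk <- max(v)
  if (pk <= 0) return(1)
  base <- quantile(v, baseline_q, names = FALSE)
  min(pk / max(base, pk / cap), cap)
}

#' Trace-stimulus cross-correlation matrix
#'
#' Entry (m, n) is the Pearson correlation between trace m and the binary
#' waveform of stimulus n, evaluated at the lag (within +- one pulse width)
#' maximizing the absolute correlation; the signed correlation at that lag is
#' stored. Zero-variance pairs give NA (reported, not thrown).
#'
#' @param traces list of `trace`s on a common uniform time grid
#' @param stimuli list of [stimulus_train()]s (rendered internally with
#'   [stimulus_waveform()] on the trace grid)
#' @return an `xcorr_matrix` (traces x stimuli) with a `lags_ms` attribute
#' @export
xcorr_matrix <- function(traces, stimuli) {
  times <- traces[[1]]$time_ms
  for (tr in traces) {
    if (length(tr$time_ms) != length(times) ||
        max(abs(tr$time_ms - times)) > 1e-9) {
      stop_invalid("all traces must share one time grid")
    }
  }
  dt <- if (length(times) > 1) times[2] - times[1] else 1
  M <- matrix(NA_real_, length(traces), length(stimuli))
  L <- matrix(NA_real_, length(traces), length(stimuli))
  for (n in seq_along(stimuli)) {
    w <- stimulus_waveform(stimuli[[n]], times)
    max_lag <- max(1L, ceiling(max(stimuli[[n]]$widths, 0) / dt))
    for (m in seq_along(traces)) {
      v <- traces[[m]]$value
      if (sd(v) == 0 || sd(w) == 0) next
      best <- 0; best_lag <- 0L
      for (lag in (-max_lag):max_lag) {
        if (lag >= 0) {
          a <- v[(1 + lag):length(v)]; b <- w[1:(length(w) - lag)]
        } else {
          a <- v[1:(length(v) + lag)]; b <- w[(1 - lag):length(w)]
        }
        if (sd(a) == 0 || sd(b) == 0) next
        r <- stats::cor(a, b)
        if (abs(r) > abs(best)) { best <- r; best_lag <- lag }
      }
      M[m, n] <- best
      L[m, n] <- best_lag * dt
    }
  }
  structure(M, lags_ms = L, class = "xcorr_matrix")
}

#' Spike-triggered average of a trace
#'
#' Aligns peri-onset snippets of the trace on the stimulus onsets, returning
#' the mean waveform, its standard error (sample SD over sqrt(n)), the number
#' of complete snippets, and the recovered pulse width (FWHM of the mean
#' waveform, ms).
#'
#' @param trace a `trace` on a uniform grid
#' @param train the [stimulus_train()] that drove the target
#' @param peri_window_ms half-window around each onset, ms
#' @return a `spike_summary`: list with `waveform` (tibble `time_ms`, `mean`,
#'   `stderr`), `n_spikes`, `recovered_width_ms`
#' @export
extract_spikes <- function(trace, train, peri_window_ms = 10) {
  times <- trace$time_ms
  dt <- times[2] - times[1]
  k <- ceiling(peri_window_ms / dt)
  rel <- (-k):k
  snippets <- list()
  for (on in train$onsets) {
    i0 <- which.min(abs(times - on))
    idx <- i0 + rel
    if (idx[1] < 1 || idx[length(idx)] > length(times)) next
    snippets[[length(snippets) + 1L]] <- trace$value[idx]
  }
  if (!length(snippets)) {
    abort("no stimulus onset lies fully inside the trace",
          class = c("evlfm_insufficient_input", "evlfm_error"))
  }
  S <- do.call(rbind, snippets)
  mw <- colMeans(S)
  se <- if (nrow(S) > 1) apply(S, 2, sd) / sqrt(nrow(S)) else rep(0, ncol(S))
  width <- tryCatch(fwhm(mw, dt), evlfm_no_peak = function(e) NA_real_)
  structure(list(waveform = tibble(time_ms = rel * dt, mean = mw, stderr = se),
                 n_spikes = nrow(S), recovered_width_ms = width),
            class = "spike_summary")
}

#' @export
print.spike_summary <- function(x, ...) {
  cat(sprintf("<spike_summary> %d spikes, recovered width %.3g ms\n",
              x$n_spikes, x$recovered_width_ms))
  invisible(x)
}

#' @export
tidy.spike_summary <- function(x, ...) x$waveform

#' @export
glance.spike_summary <- function(x, ...) {
  tibble(n_spikes = x$n_spikes, recovered_width_ms = x$recovered_width_ms)
}

# --- tracking ---------------------------------------------------------------

# detect bright blobs in one volume by iterative peak extraction:
# take the global max, compute the intensity-weighted centroid in a window
# around it, zero the window, repeat while above threshold
detect_blobs <- function(volume, threshold_q = 0.3, detect_radius_um = 3,
                         detect_radius_z_um = 2 * detect_radius_um) {
  d <- dim(volume)
  pitch <- attr(volume, "lateral_um_per_px") %||% 1
  z_planes <- attr(volume, "z_planes")
  zp <- if (length(z_planes) > 1) mean(abs(diff(z_planes))) else 1
  w_lat <- max(1L, ceiling(detect_radius_um / pitch))
  # axial suppression window is wider than lateral: shift-and-sum volumes are
  # axially elongated, and one bead must yield one detection
  w_z <- max(1L, ceiling(detect_radius_z_um / zp))
  work <- unclass(volume)
  thr <- threshold_q * max(work)
  out <- NULL
  while (TRUE) {
    k <- which.max(work)
    if (work[k] < thr || work[k] <= 0) break
    pr <- (k - 1L) %% d[1] + 1L
    pc <- ((k - 1L) %/% d[1]) %% d[2] + 1L
    pz <- (k - 1L) %/% (d[1] * d[2]) + 1L
    rr <- max(1L, pr - w_lat):min(d[1], pr + w_lat)
    cc <- max(1L, pc - w_lat):min(d[2], pc + w_lat)
    zz <- max(1L, pz - w_z):min(d[3], pz + w_z)
    blk <- work[rr, cc, zz, drop = FALSE]
    tot <- sum(blk)
    cy <- sum(slice.index(blk, 1) * blk) / tot + rr[1] - 1
    cx <- sum(slice.index(blk, 2) * blk) / tot + cc[1] - 1
    cz <- sum(slice.index(blk, 3) * blk) / tot + zz[1] - 1
    # axial position interpolated on the z-plane grid
    z_um <- approx(seq_along(z_planes), z_planes, xout = cz, rule = 2)$y
    out <- rbind(out, c((cx - 0.5) * pitch, (cy - 0.5) * pitch, z_um, tot))
    work[rr, cc, zz] <- 0
  }
  if (is.null(out)) {
    return(tibble(x = numeric(), y = numeric(), z = numeric(),
                  mass = numeric()))
  }
  tibble(x = out[, 1], y = out[, 2], z = out[, 3], mass = out[, 4])
}

#' Track bead centroids across a volume sequence
#'
#' Per-frame detection by thresholded intensity-weighted 3D centroids,
#' followed by greedy nearest-neighbour linking within `link_radius_um`;
#' unmatched detections start new tracks.
#'
#' @param volumes a `volume_sequence`
#' @param link_radius_um maximum frame-to-frame displacement, um
#' @param threshold_q detection threshold as a fraction of the volume maximum
#' @param detect_radius_um lateral centroid window half-size, um
#' @param detect_radius_z_um axial suppression half-size, um (default twice
#'   the lateral radius, covering the axial elongation of refocused beads)
#' @return a `track_set` tibble: `id`, `time_ms`, `x_um`, `y_um`, `z_um`
#' @export
track_centroids <- function(volumes, link_radius_um = 10, threshold_q = 0.3,
                            detect_radius_um = 3,
                            detect_radius_z_um = 2 * detect_radius_um) {
  if (length(volumes$volumes) < 2) {
    abort("at least two volumes are required",
          class = c("evlfm_insufficient_input", "evlfm_error"))
  }
  rows <- list()
  open_pos <- NULL    # matrix of last positions per open track
  open_id <- integer(0)
  next_id <- 1L
  for (k in seq_along(volumes$volumes)) {
    det <- detect_blobs(volumes$volumes[[k]], threshold_q, detect_radius_um,
                        detect_radius_z_um)
    tk <- volumes$times_ms[k]
    if (!nrow(det)) { next }
    P <- as.matrix(det[, c("x", "y", "z")])
    assigned <- rep(NA_integer_, nrow(P))
    if (length(open_id)) {
      D <- as.matrix(stats::dist(rbind(open_pos, P)))
      D <- D[seq_len(nrow(open_pos)), -seq_len(nrow(open_pos)), drop = FALSE]
      D[D > link_radius_um] <- NA
      used_tr <- logical(nrow(D)); used_dt <- logical(ncol(D))
      repeat {
        if (all(is.na(D))) break
        k2 <- which.min(D)
        i <- (k2 - 1L) %% nrow(D) + 1L; j <- (k2 - 1L) %/% nrow(D) + 1L
        assigned[j] <- open_id[i]
        used_tr[i] <- TRUE; used_dt[j] <- TRUE
        D[i, ] <- NA; D[, j] <- NA
      }
    }
    new_pos <- matrix(0, 0, 3); new_id <- integer(0)
    for (j in seq_len(nrow(P))) {
      id <- assigned[j]
      if (is.na(id)) { id <- next_id; next_id <- next_id + 1L }
      rows[[length(rows) + 1L]] <- tibble(id = id, time_ms = tk,
                                          x_um = P[j, 1], y_um = P[j, 2],
                                          z_um = P[j, 3])
      new_pos <- rbind(new_pos, P[j, ]); new_id <- c(new_id, id)
    }
    open_pos <- new_pos; open_id <- new_id
  }
  out <- if (length(rows)) dplyr::bind_rows(rows) else {
    tibble(id = integer(), time_ms = numeric(), x_um = numeric(),
           y_um = numeric(), z_um = numeric())
  }
  structure(dplyr::arrange(out, .data$id, .data$time_ms),
            class = c("track_set", class(tibble())))
}

#' @export
tidy.track_set <- function(x, ...) as_tibble(x)

#' Speed of a track from a linear position-time fit
#'
#' Least-squares linear fit of each coordinate against time; the speed is the
#' Euclidean norm of the fitted velocity. With several tracks in the input, a
#' tibble of per-track speeds is returned.
#'
#' @param track a `track_set` (or any tibble with `id`, `time_ms`, `x_um`,
#'   `y_um`, `z_um`)
#' @return speed in mm/s (scalar for a single track)
#' @export
estimate_velocity <- function(track) {
  one <- function(df) {
    if (nrow(df) < 2) {
      abort("at least two track points are required",
            class = c("evlfm_insufficient_input", "evlfm_error"))
    }
    t <- df$time_ms
    v <- vapply(c("x_um", "y_um", "z_um"), function(cn) {
      unname(coef(lm(df[[cn]] ~ t))[2])
    }, numeric(1))
    sqrt(sum(v^2))     # um/ms = mm/s
  }
  ids <- unique(track$id)
  if (length(ids) <= 1) return(one(track))
  # multi-track form: spurious single-point tracks are dropped, not errors
  ids <- ids[vapply(ids, function(i) sum(track$id == i) >= 2, logical(1))]
  tibble(id = ids,
         speed_mm_s = vapply(ids, function(i) one(track[track$id == i, ]),
                             numeric(1)))
}

# --- losses and the enhancement interface -----------------------------------

#' Mean absolute error
#'
#' @param y,x equally shaped numeric arrays
#' @return scalar MAE
#' @export
mae <- function(y, x) {
  if (!identical(dim(y) %||% length(y), dim(x) %||% length(x))) {
    stop_invalid("`y` and `x` must have identical shape")
  }
  mean(abs(y - x))
}

#' Normalized Pearson correlation coefficient
#'
#' @param y,x equally shaped numeric arrays with nonzero variance
#' @return correlation in `[-1, 1]`
#' @export
npcc <- function(y, x) {
  if (!identical(dim(y) %||% length(y), dim(x) %||% length(x))) {
    stop_invalid("`y` and `x` must have identical shape")
  }
  yv <- as.numeric(y) - mean(y); xv <- as.numeric(x) - mean(x)
  den <- sqrt(sum(yv^2)) * sqrt(sum(xv^2))
  if (den == 0) {
    abort("zero variance: correlation undefined",
          class = c("evlfm_undefined_correlation", "evlfm_error"))
  }
  sum(yv * xv) / den
}

#' Combined reconstruction loss
#'
#' `total_loss = mae - npcc`; a perfect prediction scores -1.
#'
#' @param y,x equally shaped numeric arrays
#' @return scalar loss
#' @export
total_loss <- function(y, x) mae(y, x) - npcc(y, x)

#' Apply a volume-to-volume enhancement transform
#'
#' Pluggable interface for learned or analytic post-reconstruction
#' enhancement: any function mapping a volume to an equally shaped volume
#' (default: identity). Attributes of the input are preserved.
#'
#' @param volume a `refocused_volume`
#' @param transform function of one volume argument
#' @return enhanced volume
#' @export
apply_enhancement <- function(volume, transform = identity) {
  out <- transform(unclass(volume))
  if (!identical(dim(out), dim(unclass(volume)))) {
    stop_invalid("enhancement must preserve the volume shape")
  }
  attributes(out) <- attributes(volume)
  out
}
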