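# refocus: crop frames into sub-aperture views, shift-and-sum volumetric
# refocusing, PSF calibration from a translating bead, 3D MTF, SNR gain

#' Calibrate sub-aperture view centers
#'
#' With a [system_geometry()], returns the exact tile centers. With a 2D
#' reference frame (e.g. a summed PSF frame), detects view spots by iterative
#' peak extraction and snaps them to the best-fit regular grid.
#'
#' @param reference a [system_geometry()] or a matrix
#' @param grid_side views per side when `reference` is a matrix
#' @param view_size crop size, px, when `reference` is a matrix (default:
#'   estimated grid pitch)
#' @return a `view_centers` tibble with columns `u`, `v`, `row0`, `col0`
#'   (1-based top-left crop corners), `row_c`, `col_c` and attributes
#'   `view_size`, `grid_side`
#' @export
calibrate_view_centers <- function(reference, grid_side = 5, view_size = NULL) {
  if (inherits(reference, "system_geometry")) {
    tops <- view_tops(reference)
    return(structure(tops, view_size = reference$view_size,
                     grid_side = reference$grid_side,
                     class = c("view_centers", class(tops))))
  }
  img <- blur_gauss(unclass(reference), 1)
  s <- grid_side
  need <- s * s
  peaks <- matrix(0, 0, 2)
  work <- img
  thr <- 0.2 * max(work)
  suppress <- max(4L, floor(min(dim(img)) / (2L * s)))
  while (nrow(peaks) < need && max(work) > thr) {
    k <- which.max(work)
    r <- (k - 1L) %% nrow(work) + 1L; c <- (k - 1L) %/% nrow(work) + 1L
    peaks <- rbind(peaks, c(r, c))
    rr <- max(1, r - suppress):min(nrow(work), r + suppress)
    cc <- max(1, c - suppress):min(ncol(work), c + suppress)
    work[rr, cc] <- 0
  }
  if (nrow(peaks) < need) {
    abort(sprintf("view calibration failed: %d of %d spots detected",
                  nrow(peaks), need),
          class = c("evlfm_calibration_error", "evlfm_error"))
  }
  # snap to the best-fit regular grid: cluster rows/cols and fit pitch
  fit_axis <- function(v) {
    v <- sort(v)
    groups <- cumsum(c(1, diff(v) > suppress))
    centers <- tapply(v, groups, mean)
    if (length(centers) != s) {
      abort("view calibration failed: detected spots do not form a grid",
            class = c("evlfm_calibration_error", "evlfm_error"))
    }
    co <- coef(lm(centers ~ seq_len(s)))
    list(pitch = co[2], pos = co[1] + co[2] * seq_len(s))
  }
  fr <- fit_axis(peaks[, 1]); fc <- fit_axis(peaks[, 2])
  pitch <- mean(c(fr$pitch, fc$pitch))
  vs <- view_size %||% (2 * floor(pitch / 2))
  idx <- (-(s - 1) %/% 2):((s - 1) %/% 2)
  grid <- expand.grid(v = idx, u = idx)
  row_c <- fr$pos[match(grid$v, idx)]
  col_c <- fc$pos[match(grid$u, idx)]
  tops <- tibble(u = grid$u, v = grid$v,
                 row0 = round_half_up(row_c - (vs + 1) / 2) + 1L,
                 col0 = round_half_up(col_c - (vs + 1) / 2) + 1L,
                 row_c = row_c, col_c = col_c)
  structure(tops, view_size = as.integer(vs), grid_side = s,
            class = c("view_centers", class(tops)))
}

#' Crop a frame into sub-aperture views
#'
#' @param frame a `ts_frame` or matrix
#' @param centers a `view_centers` (from [calibrate_view_centers()])
#' @param lateral_um_per_px object-space sampling carried to downstream
#'   volumes, um per view pixel
#' @return a `view_set`
#' @export
crop_views <- function(frame, centers, lateral_um_per_px = 1) {
  vs <- attr(centers, "view_size")
  s <- attr(centers, "grid_side")
  img <- unclass(frame)
  idx <- sort(unique(centers$u))
  out <- array(0, c(vs, vs, s, s))
  for (k in seq_len(nrow(centers))) {
    r <- centers$row0[k]; c <- centers$col0[k]
    if (r < 1 || c < 1 || r + vs - 1 > nrow(img) || c + vs - 1 > ncol(img)) {
      stop_invalid(sprintf("view (%d, %d) crop out of bounds",
                           centers$u[k], centers$v[k]))
    }
    a <- match(centers$v[k], idx); b <- match(centers$u[k], idx)
    out[, , a, b] <- img[r:(r + vs - 1), c:(c + vs - 1)]
  }
  structure(out, uv = idx, lateral_um_per_px = lateral_um_per_px,
            t_frame_ms = attr(frame, "t_frame_ms"), class = "view_set")
}

#' Shift-and-sum volumetric refocusing
#'
#' The slice at depth `z` is the mean over views of view `(u, v)` translated
#' by `(-u * alpha * z, -v * alpha * z)` pixels (the negatives of the forward
#' disparities, so forward projection followed by refocusing brings a source
#' back into focus at its depth). Subpixel shifts use bilinear interpolation
#' with zero padding; `"nearest"` gives the bit-exact integer-shift path.
#'
#' @param views a `view_set`
#' @param alpha disparity slope, px/um
#' @param depths depths to reconstruct, um
#' @param interp `"bilinear"` or `"nearest"`
#' @return a `refocused_volume`: 3D array `[y, x, z]` with attributes
#'   `z_planes`, `lateral_um_per_px`, `provenance`
#' @export
refocus_volume <- function(views, alpha, depths, interp = "bilinear") {
  if (!length(depths)) stop_invalid("`depths` must be non-empty")
  if (alpha < 0) stop_invalid("`alpha` must be >= 0")
  d <- dim(views)
  idx <- attr(views, "uv")
  vol <- array(0, c(d[1], d[2], length(depths)))
  nv <- d[3] * d[4]
  for (kz in seq_along(depths)) {
    z <- depths[kz]
    acc <- matrix(0, d[1], d[2])
    for (a in seq_len(d[3])) {
      for (b in seq_len(d[4])) {
        acc <- acc + shift_image(views[, , a, b], -idx[b] * alpha * z,
                                 -idx[a] * alpha * z, interp)
      }
    }
    vol[, , kz] <- acc / nv
  }
  structure(vol, z_planes = as.numeric(depths),
            lateral_um_per_px = attr(views, "lateral_um_per_px") %||% 1,
            provenance = list(t_frame_ms = attr(views, "t_frame_ms"),
                              alpha = alpha, interp = interp),
            class = "refocused_volume")
}

#' @export
print.refocused_volume <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<refocused_volume> %dx%d px x %d planes, z in [%g, %g] um\n",
              d[1], d[2], d[3], min(attr(x, "z_planes")),
              max(attr(x, "z_planes"))))
  invisible(x)
}

#' Threshold cleanup of refocusing ghosts
#'
#' Sets voxels below a threshold to zero; the rest are unchanged. The
#' threshold is `q * max(volume)` (quantile-of-max convention) or an absolute
#' level. Degenerate `q` is clamped to `[0, 1]`.
#'
#' @param volume a `refocused_volume`
#' @param q relative threshold as a fraction of the volume maximum
#' @param absolute absolute threshold overriding `q`
#' @return cleaned volume, same class and attributes
#' @export
threshold_clean <- function(volume, q = 0.1, absolute = NULL) {
  thr <- if (!is.null(absolute)) absolute else {
    q <- min(max(q, 0), 1)
    q * max(volume)
  }
  out <- volume
  out[out < thr] <- 0
  out
}

#' Calibrate a PSF stack from a translating-bead event stream
#'
#' A bead translating axially at constant speed traverses the depth of field;
#' frames reconstructed at interval `delta_ms` are mapped to depths
#' `z(t) = z0 + v t` (0.2 mm/s gives 0.2 um per ms) and each frame becomes
#' the PSF at its depth label. `z0` defaults to minus half the traversal span.
#'
#' @param stream an [event_stream()] of the traversal
#' @param axial_speed_mm_s traversal speed, mm/s
#' @param delta_ms accumulation window, ms
#' @param tau_ms time-surface decay, ms
#' @param z0_um starting depth, um (default `-span/2`)
#' @param polarity_mode time-surface polarity mode
#' @param geometry optional [system_geometry()] attached to the stack (enables
#'   central-view cropping in [as_psf_array()])
#' @return a `psf_stack`
#' @export
psf_from_translating_bead <- function(stream, axial_speed_mm_s, delta_ms,
                                      tau_ms = delta_ms / 3, z0_um = NULL,
                                      polarity_mode = "combined",
                                      geometry = NULL) {
  check_scalar_pos(axial_speed_mm_s, "axial_speed_mm_s")
  span <- stream_span_ms(stream)
  if (diff(span) < delta_ms) {
    abort("stream shorter than one accumulation window",
          class = c("evlfm_insufficient_input", "evlfm_error"))
  }
  fs <- frame_sequence(stream, delta_ms, tau_ms = tau_ms,
                       polarity_mode = polarity_mode)
  travel <- axial_speed_mm_s * diff(span)       # um
  z0 <- z0_um %||% (-travel / 2)
  depths <- z0 + axial_speed_mm_s * (fs$times_ms - span[1])
  psf_stack(lapply(fs$frames, unclass), depths, geometry)
}

#' 3D modulation transfer function
#'
#' Magnitude of the 3D discrete Fourier transform of a 3D PSF, normalized to
#' 1 at zero frequency and centered (zero frequency at the middle index).
#'
#' @param psf 3D PSF array, or a `psf_stack` (stacked with [as_psf_array()])
#' @param crop passed to [as_psf_array()] for `psf_stack` input
#' @return an `mtf_volume`: 3D array with attribute `freq` (cycles/sample per
#'   axis) and `zero_index`
#' @export
mtf3d <- function(psf, crop = "full") {
  if (inherits(psf, "psf_stack")) psf <- as_psf_array(psf, crop = crop)
  if (!length(psf) || all(psf == 0)) {
    stop_invalid("PSF must have positive total energy")
  }
  M <- abs(fft(array(as.numeric(psf), dim(psf))))
  M <- M / M[1, 1, 1]
  d <- dim(M)
  shift1 <- function(n) c((floor(n / 2) + 1):n, 1:floor(n / 2))
  M <- M[shift1(d[1]), shift1(d[2]), shift1(d[3])]
  freq <- lapply(d, function(n) {
    (seq_len(n) - (floor(n / 2) + 1)) / n
  })
  structure(M, freq = freq, zero_index = floor(d / 2) + 1,
            class = "mtf_volume")
}

#' SNR gain of shift-and-sum over a single view
#'
#' SNR is the peak in the signal ROI divided by the standard deviation in the
#' background ROI; the gain is the refocused slice's SNR over the median
#' per-view SNR. Averaging N views with uncorrelated noise yields a sqrt(N)
#' gain (5x for a 5x5 grid).
#'
#' @param views a `view_set`
#' @param refocused_slice 2D in-focus slice reconstructed from the views
#' @param signal_roi,background_roi disjoint logical masks (view-sized)
#' @return gain ratio (scalar)
#' @export
snr_gain <- function(views, refocused_slice, signal_roi, background_roi) {
  if (any(signal_roi & background_roi)) {
    stop_invalid("signal and background ROIs must be disjoint")
  }
  snr_of <- function(img) {
    s <- sd(img[background_roi])
    if (!is.finite(s) || s == 0) {
      abort("background ROI has zero variance: SNR undefined",
            class = c("evlfm_undefined_snr", "evlfm_error"))
    }
    max(img[signal_roi]) / s
  }
  d <- dim(views)
  per_view <- vapply(seq_len(d[3] * d[4]), function(k) {
    a <- (k - 1L) %% d[3] + 1L; b <- (k - 1L) %/% d[3] + 1L
    snr_of(views[, , a, b])
  }, numeric(1))
  snr_of(refocused_slice) / median(per_view)
}
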