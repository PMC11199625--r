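# characterization suite: self-contained simulated experiments exercising the
# full simulate -> events -> frames -> refocus -> analysis chain.
# Problem sizes are scaled to desk-top runs (small sensors, single/few beads);
# the methods vignette discusses the choices.

#' Compact simulation geometry
#'
#' A scaled-down 5x5 system used by the characterization experiments: square
#' sensor of `grid_side * view_pitch` pixels, 1 um object-space sampling.
#'
#' @param view_size view side, px
#' @param z_range axial range, um
#' @param ... passed to [system_geometry()]
#' @return a [system_geometry()]
#' @export
sim_geometry <- function(view_size = 24, z_range = c(-10, 10), ...) {
  system_geometry(grid_side = 5, view_size = view_size,
                  view_pitch = view_size, z_range = z_range,
                  lateral_um_per_px = 1, ...)
}

#' Frame-rate law of the accumulation window
#'
#' Converts a synthetic event stream spanning `span_ms` with window
#' `delta_ms` and reports the frame count and effective frame rate
#' (`1000 / delta_ms` Hz; 1 ms -> 1 kHz, 2 ms -> 500 Hz).
#'
#' @param delta_ms accumulation window, ms
#' @param span_ms stream span, ms
#' @param seed integer seed
#' @return list with `n_frames`, `frame_rate_hz`
#' @export
experiment_frame_rate <- function(delta_ms, span_ms, seed = 1) {
  ev <- with_seed_(seed, tibble(
    x = sample.int(32, 500, replace = TRUE) - 1L,
    y = sample.int(32, 500, replace = TRUE) - 1L,
    t = sort(round(runif(500, 0, span_ms * 1000))),
    p = sample(c(-1L, 1L), 500, replace = TRUE)))
  stream <- event_stream(ev, sensor_shape = c(32, 32))
  fs <- frame_sequence(stream, delta_ms, t_start_ms = 0, t_end_ms = span_ms)
  list(n_frames = length(fs$frames), frame_rate_hz = fs$frame_rate_hz)
}

#' SNR gain of shift-and-sum refocusing
#'
#' N views carry an identical in-focus signal plus i.i.d. Gaussian noise; the
#' in-focus refocused slice (zero disparity) is compared to a single view.
#' The expected gain is sqrt(N): 5x for the 5x5 grid.
#'
#' @param grid_sides view-grid sides to test (N = side^2)
#' @param n_trials Monte-Carlo trials per grid size
#' @param seed integer seed
#' @return tibble with `n_views`, `gain`, `expected`
#' @export
experiment_snr_gain <- function(grid_sides = c(2, 3, 4, 5), n_trials = 100,
                                seed = 1) {
  sz <- 32L
  xy <- outer(exp(-((1:sz) - 16.5)^2 / (2 * 2^2)),
              exp(-((1:sz) - 16.5)^2 / (2 * 2^2)))
  # strong signal (peak 100 over unit noise) so the max-statistic bias of the
  # peak/sd SNR estimator is negligible against the sqrt(N) law
  signal <- 100 * xy
  sig_roi <- xy > 0.5
  bg_roi <- matrix(FALSE, sz, sz); bg_roi[1:8, ] <- TRUE
  with_seed_(seed, {
    rows <- lapply(grid_sides, function(s) {
      n <- s * s
      hw <- (s - 1) / 2
      uv <- seq(-hw, hw)
      gains <- vapply(seq_len(n_trials), function(i) {
        arr <- array(0, c(sz, sz, s, s))
        for (k in seq_len(n)) {
          arr[, , (k - 1) %% s + 1, (k - 1) %/% s + 1] <-
            signal + matrix(rnorm(sz * sz), sz, sz)
        }
        views <- structure(arr, uv = uv, lateral_um_per_px = 1,
                           class = "view_set")
        vol <- refocus_volume(views, alpha = 0, depths = 0)
        snr_gain(views, vol[, , 1], sig_roi, bg_roi)
      }, numeric(1))
      tibble(n_views = n, gain = mean(gains), expected = sqrt(n))
    })
    dplyr::bind_rows(rows)
  })
}

#' Pulse timing of a blinking source
#'
#' A static bead is pulsed (1 ms width, 3 ms onset-to-onset period by
#' default), recorded, and reconstructed at a 1 ms window from the
#' positive-polarity time surface with median denoising. Reports the number
#' of empty frames between consecutive signal-bearing frames (2 for a 1 ms
#' pulse with a 2 ms OFF delay).
#'
#' @param width_ms pulse width, ms
#' @param interval_ms onset-to-onset period, ms
#' @param duration_ms recording length, ms
#' @param seed integer seed
#' @return list with `gaps` (empty-frame counts between signal frames),
#'   `modal_gap`, `n_signal_frames`
#' @export
experiment_blink_timing <- function(width_ms = 1, interval_ms = 3,
                                    duration_ms = 45, seed = 1) {
  geom <- sim_geometry()
  train <- make_pulse_train(width_ms, interval = interval_ms,
                            duration_ms = duration_ms)
  bead <- bead_object(traj_static(c(12, 12, 10)), radius_um = 1,
                      brightness = 100, stimulus = train)
  scene <- scene_spec(list(bead), extent_um = c(24, 24, 20),
                      voxel_pitch_um = 1, duration_ms = duration_ms,
                      seed = seed)
  stream <- simulate_recording(scene, geom, sensor_config(), 0.25, seed)
  # accumulation windows centered on the pulse onsets (frames synchronized to
  # the first pulse), so each onset response falls into exactly one window
  fs <- frame_sequence(stream, 1, t_start_ms = -0.5,
                       t_end_ms = duration_ms - 0.5,
                       polarity_mode = "positive")
  fs <- denoise_sequence(fs, 3)
  signal <- which(vapply(fs$frames, function(f) sum(f) > 0, logical(1)))
  gaps <- diff(signal) - 1L
  list(gaps = gaps,
       modal_gap = if (length(gaps)) as.integer(names(which.max(table(gaps))))
                   else NA_integer_,
       n_signal_frames = length(signal))
}

#' Recovered pulse width across stimulus widths
#'
#' For each width, a static bead is driven by a flickering pulse train,
#' recorded, refocused at the bead depth, and the spike-triggered average of
#' the ROI trace is measured with [extract_spikes()].
#'
#' @param widths_ms pulse widths to test, ms
#' @param seed integer seed
#' @return tibble with `width_ms`, `recovered_width_ms`, `error_ms`
#' @export
experiment_pulse_width <- function(widths_ms = 1:6, seed = 1) {
  geom <- sim_geometry()
  delta <- 1
  rows <- lapply(widths_ms, function(w) {
    onsets <- seq(20, 220, by = 40)
    train <- stimulus_train(onsets, rep(w, length(onsets)),
                            flicker_hz = 1000)
    bead <- bead_object(traj_static(c(12, 12, 10)), stimulus = train)
    scene <- scene_spec(list(bead), extent_um = c(24, 24, 20),
                        voxel_pitch_um = 1, duration_ms = 250, seed = seed)
    stream <- simulate_recording(scene, geom, sensor_config(), 0.25,
                                 seed + w)
    # windows centered on the (integer) onsets; tau = 2 * delta keeps the
    # flicker-sustained plateau above half the onset response
    vols <- reconstruct_volumes(stream, geom, delta, depths = 0,
                                tau_ms = 2 * delta, polarity_mode = "positive",
                                t_start_ms = -0.5, t_end_ms = 249.5)
    roi <- array(FALSE, dim(vols$volumes[[1]]))
    roi[10:15, 10:15, 1] <- TRUE
    tr <- extract_trace(vols, roi)
    sp <- extract_spikes(tr, train, peri_window_ms = 12)
    tibble(width_ms = w, recovered_width_ms = sp$recovered_width_ms,
           error_ms = abs(sp$recovered_width_ms - w))
  })
  dplyr::bind_rows(rows)
}

#' Spike-train cross-correlation experiment
#'
#' `n_targets` static targets at distinct 3D positions are driven by unique
#' random spike trains (widths 1-6 ms, intervals 100-600 ms), recorded
#' through the full chain, refocused, and per-target ROI traces are
#' correlated against the ground-truth stimulus waveforms.
#'
#' @param n_targets number of targets
#' @param duration_ms recording length, ms
#' @param seed integer seed
#' @return list with `xcorr` (the matrix), `diag_mean`, `offdiag_mean`,
#'   `traces`, `trains`
#' @export
experiment_spike_xcorr <- function(n_targets = 12, duration_ms = 2400,
                                   seed = 1) {
  geom <- sim_geometry()
  delta <- 1
  trains <- make_spike_trains(n_targets, duration_ms = duration_ms,
                              seed = seed)
  xs <- seq(4.5, 19.5, length.out = 4)
  ys <- seq(5, 19, length.out = 3)
  zs <- c(4, 10, 16)       # scene z; maps to -6, 0, 6 um depth
  pos <- expand.grid(x = xs, y = ys)
  objects <- lapply(seq_len(n_targets), function(i) {
    p <- c(pos$x[(i - 1) %% nrow(pos) + 1], pos$y[(i - 1) %% nrow(pos) + 1],
           zs[(i - 1) %% 3 + 1])
    bead_object(traj_static(p), radius_um = 1, brightness = 100,
                stimulus = trains[[i]])
  })
  scene <- scene_spec(objects, extent_um = c(24, 24, 20), voxel_pitch_um = 1,
                      duration_ms = duration_ms, seed = seed)
  stream <- simulate_recording(scene, geom, sensor_config(), 0.25, seed)
  depths <- c(-6, 0, 6)
  vols <- reconstruct_volumes(stream, geom, delta, depths, tau_ms = 2 * delta,
                              polarity_mode = "positive",
                              t_start_ms = 0, t_end_ms = duration_ms)
  d <- dim(vols$volumes[[1]])
  traces <- lapply(seq_len(n_targets), function(i) {
    p <- c(pos$x[(i - 1) %% nrow(pos) + 1], pos$y[(i - 1) %% nrow(pos) + 1])
    zi <- (i - 1) %% 3 + 1
    roi <- array(FALSE, d)
    rr <- pmax(1, round(p[2]) - 1):pmin(d[1], round(p[2]) + 1)
    cc <- pmax(1, round(p[1]) - 1):pmin(d[2], round(p[1]) + 1)
    roi[rr, cc, zi] <- TRUE
    extract_trace(vols, roi)
  })
  M <- xcorr_matrix(traces, trains)
  dg <- diag(unclass(M))
  off <- unclass(M)[row(M) != col(M)]
  list(xcorr = M, diag_mean = mean(dg, na.rm = TRUE),
       offdiag_mean = mean(abs(off), na.rm = TRUE), traces = traces,
       trains = trains)
}

#' Speed recovery and resolution stability across bead velocities
#'
#' For each programmed speed a single-bead linear-motion phantom is recorded,
#' reconstructed at a 1 ms window, tracked, and its speed re-estimated from
#' the track; lateral (cross-motion) and axial FWHM are measured on a
#' mid-sequence volume. Slower beads are observed for longer so each run
#' accumulates a comparable displacement.
#'
#' @param speeds_mm_s programmed speeds, mm/s
#' @param seed integer seed
#' @return tibble: `speed_mm_s`, `recovered_mm_s`, `rel_error`,
#'   `lateral_fwhm_um`, `axial_fwhm_um`
#' @export
experiment_speed_series <- function(speeds_mm_s = c(0.1, 0.5, 1.0, 2.5),
                                    seed = 1) {
  geom <- sim_geometry(view_size = 96, z_range = c(-20, 20))
  depths <- seq(-15, 15, by = 3)
  rows <- lapply(speeds_mm_s, function(v) {
    # observe as long as the bead stays inside the FOV (<= ~64 um of travel),
    # longer for slow beads whose velocity fit is variance-limited
    dur <- min(240, max(24, floor(64 / max(v, 0.25))))
    scene <- make_linear_motion_phantom(
      1, extent_um = c(96, 96, 40), thickness_um = 12, speed_mm_s = v,
      duration_ms = dur, direction = c(0, 1, 0), voxel_pitch_um = c(1, 1, 2),
      seed = seed)
    stream <- simulate_recording(scene, geom, sensor_config(), 0.25,
                                 seed + round(100 * v))
    vols <- reconstruct_volumes(stream, geom, 1, depths,
                                denoise_kernel = 3,
                                t_start_ms = 0, t_end_ms = dur)
    # lateral suppression window covers the full motion streak so a single
    # bead yields a single detection per frame
    tracks <- track_centroids(vols, link_radius_um = 8, threshold_q = 0.35,
                              detect_radius_um = 10, detect_radius_z_um = 12)
    # keep the longest track
    main_id <- names(which.max(table(tracks$id)))
    tr <- tracks[tracks$id == as.integer(main_id), ]
    rec <- estimate_velocity(tr)
    mid <- vols$volumes[[max(2, floor(length(vols$volumes) / 2))]]
    pitch <- attr(mid, "lateral_um_per_px")
    mrow <- tr[which.min(abs(tr$time_ms - attr(mid, "provenance")$t_frame_ms)), ]
    seed_pt <- c(round(mrow$y_um / pitch + 0.5), round(mrow$x_um / pitch + 0.5),
                 which.min(abs(depths - mrow$z_um)))
    rep <- resolution_report(mid, seed_pt)
    tibble(speed_mm_s = v, recovered_mm_s = rec,
           rel_error = abs(rec - v) / v,
           lateral_fwhm_um = rep$lateral_fwhm_um,
           axial_fwhm_um = rep$axial_fwhm_um)
  })
  dplyr::bind_rows(rows)
}

#' Background suppression of event-based readout
#'
#' A blinking bead over a bright, slowly drifting background is imaged both
#' directly (intensity frames) and through the event pipeline; the
#' peak-to-baseline contrast of the two ROI traces is compared. Because the
#' background drifts far more slowly than the accumulation window it rarely
#' crosses the contrast threshold and is strongly suppressed in the event
#' path.
#'
#' @param seed integer seed
#' @param duration_ms recording length, ms
#' @return list with `event_contrast`, `intensity_contrast`, `ratio`
#' @export
experiment_background_suppression <- function(seed = 1, duration_ms = 100) {
  geom <- sim_geometry()
  train <- make_pulse_train(1, interval = 10, duration_ms = duration_ms)
  bead <- bead_object(traj_static(c(12, 12, 10)), brightness = 100,
                      stimulus = train)
  scene <- scene_spec(list(bead), extent_um = c(24, 24, 20),
                      voxel_pitch_um = 1, duration_ms = duration_ms,
                      background = background_spec(5, drift_timescale_ms = 1000,
                                                   spatial_corr_um = 5),
                      seed = seed)
  stream <- simulate_recording(scene, geom, sensor_config(), 0.25, seed)
  fs <- frame_sequence(stream, 1, t_start_ms = 0, t_end_ms = duration_ms,
                       tau_ms = 1, polarity_mode = "positive")
  roi <- matrix(FALSE, geom$sensor_shape[2], geom$sensor_shape[1])
  tops <- view_tops(geom)
  ctr <- tops[tops$u == 0 & tops$v == 0, ]
  roi[(ctr$row0 + 9):(ctr$row0 + 14), (ctr$col0 + 9):(ctr$col0 + 14)] <- TRUE
  ev_trace <- extract_trace(fs, roi)
  rendered <- render_sensor_sequence(scene, geom, seq(1, duration_ms, by = 1))
  direct <- structure(list(frames = rendered$frames,
                           times_ms = rendered$times_ms,
                           delta_ms = 1, frame_rate_hz = 1000),
                      class = "frame_sequence")
  in_trace <- extract_trace(direct, roi)
  ec <- trace_contrast(ev_trace)
  ic <- trace_contrast(in_trace)
  list(event_contrast = ec, intensity_contrast = ic, ratio = ec / ic)
}

#' Event-derived versus direct-intensity PSF/MTF agreement
#'
#' A fluorescent bead translates axially through the depth of field at
#' `speed_mm_s` under modulated (1 kHz square-wave) illumination; the
#' event-derived PSF stack (translating-bead calibration, median-denoised) is
#' compared to the direct-intensity PSF stack of the same bead imaged through
#' the same geometry. Agreement is the cosine similarity of the maximum
#' intensity projections (lateral and axial) of the two 3D MTFs, the
#' projection-level comparison used to validate the spatial response.
#' Modulated illumination is what makes a quasi-static source visible to a
#' contrast sensor at all; see the methods vignette.
#'
#' @param speed_mm_s axial traversal speed, mm/s
#' @param seed integer seed
#' @return list with `cosine` (concatenated lateral+axial MIP cosine),
#'   `cosine_lateral`, `cosine_axial`, `event_psf`, `direct_psf`
#' @export
experiment_psf_mtf <- function(speed_mm_s = 0.2, seed = 1) {
  geom <- sim_geometry(view_size = 32, z_range = c(-10, 10))
  dur <- 95
  illum <- stimulus_train(0, dur, flicker_hz = 1000, flicker_depth = 0.5)
  bead <- bead_object(traj_linear(c(16, 16, 0.5), c(0, 0, 1), speed_mm_s),
                      stimulus = illum)
  scene <- scene_spec(list(bead), extent_um = c(32, 32, 20),
                      voxel_pitch_um = 1, duration_ms = dur, seed = seed)
  stream <- simulate_recording(scene, geom,
                               sensor_config(noise_rate = 0.05), 0.25, seed)
  ev_psf <- psf_from_translating_bead(stream, speed_mm_s, delta_ms = 1,
                                      tau_ms = 1, geometry = geom)
  ev_psf$images <- lapply(ev_psf$images, median_filter, kernel = 3L)
  direct <- synth_psf_stack(geom, ev_psf$depths_um, bead_source(geom, 1))
  me <- unclass(mtf3d(ev_psf))
  md <- unclass(mtf3d(direct))
  ml_e <- apply(me, c(1, 2), max); ml_d <- apply(md, c(1, 2), max)
  ma_e <- apply(me, c(2, 3), max); ma_d <- apply(md, c(2, 3), max)
  list(cosine = cosine_sim(c(ml_e, ma_e), c(ml_d, ma_d)),
       cosine_lateral = cosine_sim(ml_e, ml_d),
       cosine_axial = cosine_sim(ma_e, ma_d),
       event_psf = ev_psf, direct_psf = direct)
}
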