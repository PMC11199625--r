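# scene_sim: time-parameterized synthetic 3D fluorescent scenes

#' Stimulus train
#'
#' A train of illumination pulses gating the emission of a target object.
#' Pulses must be non-overlapping. An optional square-wave refresh flicker
#' emulates modulated (DMD/LED-driven) illumination: during a pulse the
#' amplitude alternates at `flicker_hz` between the nominal level and
#' `(1 - flicker_depth)` times it. Patterned-illumination hardware refreshes
#' at kHz rates; for a contrast sensor this refresh is what sustains event
#' generation over the full ON period of a static target.
#'
#' @param onsets pulse onset times, ms, strictly increasing
#' @param widths pulse widths, ms, one per onset
#' @param amplitude relative intensity scale of the illuminated state
#' @param flicker_hz square-wave refresh frequency during ON periods, Hz;
#'   0 disables flicker (constant ON level)
#' @param flicker_depth fractional modulation depth of the flicker in (0, 1)
#' @return an object of class `stimulus_train`
#' @export
stimulus_train <- function(onsets, widths, amplitude = 1,
                           flicker_hz = 0, flicker_depth = 0.5) {
  if (length(onsets) != length(widths)) {
    stop_invalid("`onsets` and `widths` must have the same length")
  }
  if (length(onsets)) {
    if (any(diff(onsets) <= 0)) stop_invalid("`onsets` must be strictly increasing")
    if (any(widths <= 0)) stop_invalid("`widths` must be positive")
    if (length(onsets) > 1 &&
        any(head(onsets, -1) + head(widths, -1) > tail(onsets, -1) + 1e-9)) {
      stop_invalid("pulses overlap: onset[i] + width[i] must not exceed onset[i+1]")
    }
  }
  if (amplitude < 0) stop_invalid("`amplitude` must be >= 0")
  structure(
    list(onsets = as.numeric(onsets), widths = as.numeric(widths),
         amplitude = amplitude, flicker_hz = flicker_hz,
         flicker_depth = flicker_depth),
    class = "stimulus_train"
  )
}

#' @export
print.stimulus_train <- function(x, ...) {
  cat(sprintf("<stimulus_train> %d pulses, amplitude %g, flicker %g Hz\n",
              length(x$onsets), x$amplitude, x$flicker_hz))
  invisible(x)
}

# instantaneous stimulus amplitude at times t (ms); 0 between pulses
stimulus_amplitude <- function(train, t) {
  if (is.null(train)) return(rep(1, length(t)))
  amp <- numeric(length(t))
  for (k in seq_along(train$onsets)) {
    on <- train$onsets[k]; w <- train$widths[k]
    inside <- t >= on & t < on + w
    if (!any(inside)) next
    a <- rep(train$amplitude, sum(inside))
    if (train$flicker_hz > 0) {
      phase <- ((t[inside] - on) * train$flicker_hz / 1000) %% 1
      a <- a * ifelse(phase < 0.5, 1, 1 - train$flicker_depth)
    }
    amp[inside] <- a
  }
  amp
}

#' Binary stimulus waveform on a time grid
#'
#' Renders a [stimulus_train()] as a 0/1 indicator sampled at the given times
#' (1 inside a pulse), the reference signal used by [xcorr_matrix()].
#'
#' @param train a [stimulus_train()]
#' @param times_ms sample times, ms
#' @return numeric vector of 0/1 values, one per time
#' @export
stimulus_waveform <- function(train, times_ms) {
  out <- numeric(length(times_ms))
  for (k in seq_along(train$onsets)) {
    out[times_ms >= train$onsets[k] &
        times_ms < train$onsets[k] + train$widths[k]] <- 1
  }
  out
}

#' Regular or randomized pulse train
#'
#' Builds a pulse train of fixed width whose onset-to-onset interval is either
#' fixed (`interval`) or drawn uniformly from `interval_range` per gap. Onsets
#' start at 0 ms and pulses are kept only while they fit inside `duration_ms`
#' (`onset + width <= duration`).
#'
#' @param width_ms pulse width, ms
#' @param interval fixed onset-to-onset interval, ms (a 1 ms pulse with a 2 ms
#'   OFF delay is `interval = 3`)
#' @param interval_range length-2 range, ms, from which each interval is drawn
#'   uniformly (used when `interval` is NULL)
#' @param duration_ms train duration, ms
#' @param seed integer seed for the randomized form
#' @inheritParams stimulus_train
#' @return a [stimulus_train()]
#' @export
make_pulse_train <- function(width_ms, interval = NULL, interval_range = NULL,
                             duration_ms, seed = NULL, amplitude = 1,
                             flicker_hz = 0) {
  check_scalar_pos(width_ms, "width_ms")
  check_scalar_pos(duration_ms, "duration_ms")
  if (is.null(interval) && is.null(interval_range)) {
    stop_invalid("supply `interval` or `interval_range`")
  }
  if (!is.null(interval)) {
    check_scalar_pos(interval, "interval")
    if (interval < width_ms) {
      stop_invalid("`interval` below `width_ms`: pulses would overlap")
    }
    onsets <- seq(0, duration_ms, by = interval)
  } else {
    if (length(interval_range) != 2 || interval_range[1] > interval_range[2]) {
      stop_invalid("`interval_range` must be c(min, max) with min <= max")
    }
    if (interval_range[1] < width_ms) {
      stop_invalid("`interval_range` lower bound below `width_ms`: pulses would overlap")
    }
    onsets <- with_seed_(seed, {
      on <- 0
      out <- numeric(0)
      while (on + width_ms <= duration_ms) {
        out <- c(out, on)
        on <- on + runif(1, interval_range[1], interval_range[2])
      }
      out
    })
  }
  onsets <- onsets[onsets + width_ms <= duration_ms]
  stimulus_train(onsets, rep(width_ms, length(onsets)), amplitude = amplitude,
                 flicker_hz = flicker_hz)
}

#' Distinct random spike trains for a set of targets
#'
#' Emulates targeted-illumination spike trains: for each target, pulse widths
#' are drawn uniformly from `width_range` and onset-to-onset intervals from
#' `interval_range`. The first onset of every train is at 0 ms; pulses are kept
#' while they fit inside `duration_ms`. Spike trains default to a 1 kHz
#' illumination refresh flicker (see [stimulus_train()]).
#'
#' @param n_targets number of targets
#' @param width_range pulse width range, ms
#' @param interval_range onset-to-onset interval range, ms
#' @param duration_ms duration, ms
#' @param seed integer seed
#' @param amplitude relative ON amplitude
#' @param flicker_hz illumination refresh frequency, Hz
#' @return list of `n_targets` [stimulus_train()] objects
#' @export
make_spike_trains <- function(n_targets, width_range = c(1, 6),
                              interval_range = c(100, 600), duration_ms,
                              seed = NULL, amplitude = 1, flicker_hz = 1000) {
  if (n_targets < 1) stop_invalid("`n_targets` must be >= 1")
  for (r in list(width_range, interval_range)) {
    if (length(r) != 2 || r[1] > r[2] || r[1] <= 0) {
      stop_invalid("ranges must be c(min, max) with 0 < min <= max")
    }
  }
  with_seed_(seed, {
    lapply(seq_len(n_targets), function(i) {
      on <- 0
      onsets <- numeric(0); widths <- numeric(0)
      repeat {
        w <- runif(1, width_range[1], width_range[2])
        if (on + w > duration_ms) break
        onsets <- c(onsets, on); widths <- c(widths, w)
        on <- on + max(w, runif(1, interval_range[1], interval_range[2]))
      }
      stimulus_train(onsets, widths, amplitude = amplitude,
                     flicker_hz = flicker_hz)
    })
  })
}

# --- trajectories (parametric, serializable) --------------------------------

#' Trajectory constructors
#'
#' Parametric, serializable trajectories for [bead_object()]s: a static
#' position, linear motion `x(t) = p0 + dir (v t + a t^2 / 2)` (speed in
#' um/ms, numerically equal to mm/s), or piecewise-linear interpolation
#' through sampled knots (used by the random-motion generator).
#'
#' @param p0 3D position, um
#' @return an `evlfm_traj` object
#' @export
traj_static <- function(p0) {
  structure(list(type = "static", p0 = as.numeric(p0)), class = "evlfm_traj")
}

#' @rdname traj_static
#' @param direction 3-vector motion direction (normalized internally)
#' @param speed speed, um/ms
#' @param accel acceleration, um/ms^2
#' @export
traj_linear <- function(p0, direction, speed, accel = 0) {
  d <- as.numeric(direction)
  d <- d / sqrt(sum(d^2))
  structure(list(type = "linear", p0 = as.numeric(p0), direction = d,
                 speed = speed, accel = accel), class = "evlfm_traj")
}

#' @rdname traj_static
#' @param times knot times, ms
#' @param positions matrix of knot positions (rows = times, cols = x, y, z um)
#' @export
traj_knots <- function(times, positions) {
  structure(list(type = "knots", times = as.numeric(times),
                 positions = as.matrix(positions)), class = "evlfm_traj")
}

# positions at times t (ms): length(t) x 3 matrix of um coordinates
traj_position <- function(traj, t) {
  switch(traj$type,
    static = matrix(traj$p0, nrow = length(t), ncol = 3, byrow = TRUE),
    linear = {
      s <- traj$speed * t + 0.5 * traj$accel * t^2
      matrix(traj$p0, nrow = length(t), ncol = 3, byrow = TRUE) +
        outer(s, traj$direction)
    },
    knots = {
      sapply(1:3, function(ax) {
        approx(traj$times, traj$positions[, ax], xout = t, rule = 2)$y
      }) |> matrix(nrow = length(t))
    },
    stop_invalid("unknown trajectory type")
  )
}

traj_is_static <- function(traj) {
  traj$type == "static" ||
    (traj$type == "linear" && traj$speed == 0 && traj$accel == 0)
}

# --- scene containers -------------------------------------------------------

#' Bead object
#'
#' A fluorescent bead rendered as an isotropic 3D Gaussian blob whose FWHM
#' equals the physical bead diameter.
#'
#' @param trajectory an internal trajectory object (see phantom constructors)
#' @param radius_um bead radius, um
#' @param brightness peak emission intensity, arbitrary units
#' @param stimulus optional [stimulus_train()] gating the bead's emission
#' @return an object of class `bead_object`
#' @export
bead_object <- function(trajectory, radius_um = 1, brightness = 100,
                        stimulus = NULL) {
  check_scalar_pos(radius_um, "radius_um")
  if (brightness < 0) stop_invalid("`brightness` must be >= 0")
  structure(list(trajectory = trajectory, radius_um = radius_um,
                 brightness = brightness, stimulus = stimulus),
            class = "bead_object")
}

#' Slowly varying background specification
#'
#' A spatially smooth, temporally slowly drifting additive background field,
#' emulating out-of-focus/scattered fluorescence. The realized field is
#' `mean_level * F(x) * g(t)` with `F` a smoothed positive random field and
#' `g` a piecewise-linear drift with knots every `drift_timescale_ms / 4`.
#'
#' @param mean_level mean background intensity, same units as bead brightness
#' @param drift_timescale_ms temporal drift scale, ms
#' @param spatial_corr_um lateral correlation length of the field, um
#' @return an object of class `background_spec`
#' @export
background_spec <- function(mean_level, drift_timescale_ms = 1000,
                            spatial_corr_um = 10) {
  if (mean_level < 0) stop_invalid("`mean_level` must be >= 0")
  check_scalar_pos(drift_timescale_ms, "drift_timescale_ms")
  structure(list(mean_level = mean_level,
                 drift_timescale_ms = drift_timescale_ms,
                 spatial_corr_um = spatial_corr_um),
            class = "background_spec")
}

#' Scene specification
#'
#' A time-parameterized 3D fluorescent scene: a volume extent with voxel
#' pitch, a set of [bead_object()]s with trajectories and optional stimulus
#' gating, and an optional [background_spec()].
#'
#' @param objects list of [bead_object()]s
#' @param extent_um c(x, y, z) volume extent, um
#' @param voxel_pitch_um um per voxel, recycled to 3 axes
#' @param duration_ms scene duration, ms
#' @param background optional [background_spec()]
#' @param seed integer seed recorded in the scene metadata (drives the
#'   background realization)
#' @param meta extra metadata list
#' @return an object of class `scene_spec`
#' @export
scene_spec <- function(objects, extent_um, voxel_pitch_um = 1, duration_ms,
                       background = NULL, seed = NULL, meta = list()) {
  check_scalar_pos(duration_ms, "duration_ms")
  if (length(extent_um) != 3 || any(extent_um <= 0)) {
    stop_invalid("`extent_um` must be three positive extents")
  }
  pitch <- rep_len(as.numeric(voxel_pitch_um), 3L)
  if (any(pitch <= 0)) stop_invalid("`voxel_pitch_um` must be positive")
  # every trajectory must stay finite over [0, duration]
  tt <- seq(0, duration_ms, length.out = 17)
  for (ob in objects) {
    if (!all(is.finite(traj_position(ob$trajectory, tt)))) {
      stop_invalid("object trajectory is not finite over the scene duration")
    }
  }
  structure(
    list(objects = objects, extent_um = as.numeric(extent_um),
         voxel_pitch_um = pitch, duration_ms = duration_ms,
         background = background, seed = seed, meta = meta,
         .cache = new.env(parent = emptyenv())),
    class = "scene_spec"
  )
}

#' @export
print.scene_spec <- function(x, ...) {
  cat(sprintf(
    "<scene_spec> %d object(s), extent %s um, pitch %s um, %g ms%s\n",
    length(x$objects), paste(x$extent_um, collapse = "x"),
    paste(signif(x$voxel_pitch_um, 3), collapse = "/"), x$duration_ms,
    if (is.null(x$background)) "" else ", background"))
  invisible(x)
}

# --- phantom generators -----------------------------------------------------

#' Linear-motion bead phantom
#'
#' Beads share one direction of motion with position
#' `x(t) = x0 + v t + a t^2 / 2`. Bead depths are drawn uniformly over a
#' central slab of the given thickness; lateral positions uniformly inside the
#' FOV with a margin. Beads whose trajectory exits the lateral FOV before the
#' end of the scene are flagged in `meta$exits_fov` (not an error).
#'
#' @param n_beads number of beads
#' @param extent_um c(x, y, z) volume extent, um
#' @param thickness_um axial slab thickness containing the beads, um
#' @param speed_mm_s initial speed, mm/s
#' @param accel_mm_s2 acceleration along the motion direction, mm/s^2
#' @param bead_radius_um bead radius, um (2 um diameter beads by default)
#' @param brightness peak bead intensity
#' @param duration_ms scene duration, ms
#' @param direction 3-vector motion direction (default +y)
#' @param voxel_pitch_um voxel pitch, um
#' @param stimulus optional [stimulus_train()] gating all beads
#' @param seed integer seed
#' @return a [scene_spec()]
#' @export
make_linear_motion_phantom <- function(n_beads, extent_um = c(64, 64, 40),
                                       thickness_um = extent_um[3] / 2,
                                       speed_mm_s, accel_mm_s2 = 0,
                                       bead_radius_um = 1, brightness = 100,
                                       duration_ms = 24,
                                       direction = c(0, 1, 0),
                                       voxel_pitch_um = 1, stimulus = NULL,
                                       seed = NULL) {
  if (n_beads < 1) stop_invalid("`n_beads` must be >= 1")
  if (speed_mm_s < 0) stop_invalid("`speed_mm_s` must be >= 0")
  if (bead_radius_um <= 0) stop_invalid("`bead_radius_um` must be positive")
  if (any(extent_um <= 0)) stop_invalid("`extent_um` must be positive")
  if (thickness_um > extent_um[3]) {
    stop_invalid("`thickness_um` exceeds the axial extent")
  }
  # a in um/ms^2 = mm/s^2 / 1000
  a_um_ms2 <- accel_mm_s2 / 1000
  margin <- 3 * bead_radius_um
  dirn <- direction / sqrt(sum(direction^2))
  disp <- speed_mm_s * duration_ms + 0.5 * a_um_ms2 * duration_ms^2
  with_seed_(seed, {
    objects <- vector("list", n_beads)
    exits <- logical(n_beads)
    for (i in seq_len(n_beads)) {
      z0 <- extent_um[3] / 2 + runif(1, -thickness_um / 2, thickness_um / 2)
      lat_lo <- c(margin, margin)
      lat_hi <- pmax(extent_um[1:2] - margin - pmax(dirn[1:2] * disp, 0),
                     lat_lo + 1e-6)
      p0 <- c(runif(1, lat_lo[1], lat_hi[1]), runif(1, lat_lo[2], lat_hi[2]),
              z0)
      pend <- p0 + dirn * disp
      exits[i] <- any(pend[1:2] < 0 | pend[1:2] > extent_um[1:2])
      objects[[i]] <- bead_object(
        traj_linear(p0, dirn, speed_mm_s, a_um_ms2),
        radius_um = bead_radius_um, brightness = brightness,
        stimulus = stimulus)
    }
    scene_spec(objects, extent_um, voxel_pitch_um, duration_ms, seed = seed,
               meta = list(kind = "linear_motion", speed_mm_s = speed_mm_s,
                           accel_mm_s2 = accel_mm_s2, exits_fov = exits))
  })
}

#' Random-motion bead phantom
#'
#' Each bead follows a smooth random 3D trajectory generated by an
#' Ornstein-Uhlenbeck velocity process (correlation time 20 ms) whose
#' stationary RMS speed equals `speed_scale_mm_s`; beads reflect off the
#' volume boundary.
#'
#' @param n_beads number of beads
#' @param extent_um volume extent, um
#' @param speed_scale_mm_s target RMS speed, mm/s
#' @param duration_ms scene duration, ms
#' @param bead_radius_um bead radius, um
#' @param brightness peak bead intensity
#' @param voxel_pitch_um voxel pitch, um
#' @param seed integer seed
#' @return a [scene_spec()]
#' @export
make_random_motion_phantom <- function(n_beads, extent_um = c(64, 64, 40),
                                       speed_scale_mm_s, duration_ms = 45,
                                       bead_radius_um = 1, brightness = 100,
                                       voxel_pitch_um = 1, seed = NULL) {
  if (n_beads < 1) stop_invalid("`n_beads` must be >= 1")
  check_scalar_pos(speed_scale_mm_s, "speed_scale_mm_s")
  dt <- 0.5                      # knot spacing, ms
  tau_c <- 20                    # velocity correlation time, ms
  rho <- exp(-dt / tau_c)
  sig_v <- speed_scale_mm_s / sqrt(3)   # per-axis stationary sd, um/ms
  times <- seq(0, duration_ms + dt, by = dt)
  margin <- 3 * bead_radius_um
  lo <- rep(margin, 3); hi <- extent_um - margin
  with_seed_(seed, {
    objects <- lapply(seq_len(n_beads), function(i) {
      p <- runif(3, lo, hi)
      v <- rnorm(3, 0, sig_v)
      pos <- matrix(0, length(times), 3)
      pos[1, ] <- p
      for (k in 2:length(times)) {
        v <- rho * v + sqrt(1 - rho^2) * rnorm(3, 0, sig_v)
        p <- p + v * dt
        # reflect at the walls, preserving speed
        for (ax in 1:3) {
          if (p[ax] < lo[ax]) { p[ax] <- 2 * lo[ax] - p[ax]; v[ax] <- -v[ax] }
          if (p[ax] > hi[ax]) { p[ax] <- 2 * hi[ax] - p[ax]; v[ax] <- -v[ax] }
        }
        pos[k, ] <- p
      }
      bead_object(traj_knots(times, pos), radius_um = bead_radius_um,
                  brightness = brightness)
    })
    scene_spec(objects, extent_um, voxel_pitch_um, duration_ms, seed = seed,
               meta = list(kind = "random_motion",
                           speed_scale_mm_s = speed_scale_mm_s))
  })
}

# --- rendering --------------------------------------------------------------

scene_grid <- function(scene) {
  n <- pmax(1L, round(scene$extent_um / scene$voxel_pitch_um))
  list(nx = n[1], ny = n[2], nz = n[3],
       # voxel centers, um, and axial planes mapped so z = 0 is mid-depth
       x = (seq_len(n[1]) - 0.5) * scene$voxel_pitch_um[1],
       y = (seq_len(n[2]) - 0.5) * scene$voxel_pitch_um[2],
       z = (seq_len(n[3]) - 0.5) * scene$voxel_pitch_um[3],
       z_planes = (seq_len(n[3]) - 0.5) * scene$voxel_pitch_um[3] -
         scene$extent_um[3] / 2)
}

# deterministic realization of the background field on the scene grid
realize_background <- function(scene) {
  cache <- scene$.cache
  if (!is.null(cache$bg)) return(cache$bg)
  bg <- scene$background
  g <- scene_grid(scene)
  seed <- (scene$seed %||% 0) + 101L
  field_g <- with_seed_(seed, {
    sig <- bg$spatial_corr_um / scene$voxel_pitch_um[1]
    field <- array(0, c(g$ny, g$nx, g$nz))
    for (k in seq_len(g$nz)) {
      f <- blur_gauss(matrix(rnorm(g$ny * g$nx), g$ny, g$nx), sig)
      f <- f - min(f)
      if (max(f) > 0) f <- f / mean(f)
      field[, , k] <- f
    }
    field <- field * bg$mean_level
    # temporal drift knots: piecewise-linear, +-10% around 1
    kt <- seq(0, scene$duration_ms + bg$drift_timescale_ms,
              by = bg$drift_timescale_ms / 4)
    kv <- pmax(0.1, 1 + 0.1 * rnorm(length(kt)))
    list(field = field, knot_t = kt, knot_v = kv)
  })
  cache$bg <- field_g
  field_g
}

background_gain <- function(scene, t) {
  bg <- realize_background(scene)
  approx(bg$knot_t, bg$knot_v, xout = t, rule = 2)$y
}

# stamp an isotropic 3D Gaussian blob (FWHM = bead diameter) into a volume
stamp_bead <- function(vol, g, pos, radius_um, peak, pitch) {
  sigma <- 2 * radius_um / (2 * sqrt(2 * log(2)))  # FWHM = diameter
  r <- ceiling(4 * sigma / pitch) + 1L
  cx <- pos[1] / pitch[1] + 0.5; cy <- pos[2] / pitch[2] + 0.5
  cz <- pos[3] / pitch[3] + 0.5
  lo <- floor(c(cx, cy, cz) - r); hi <- ceiling(c(cx, cy, cz) + r)
  n3 <- c(g$nx, g$ny, g$nz)
  if (any(hi < 1) || any(lo > n3)) return(vol)   # blob fully outside the FOV
  ix <- max(1L, lo[1]):min(n3[1], hi[1])
  iy <- max(1L, lo[2]):min(n3[2], hi[2])
  iz <- max(1L, lo[3]):min(n3[3], hi[3])
  gx <- exp(-(g$x[ix] - pos[1])^2 / (2 * sigma^2))
  gy <- exp(-(g$y[iy] - pos[2])^2 / (2 * sigma^2))
  gz <- exp(-(g$z[iz] - pos[3])^2 / (2 * sigma^2))
  blob <- outer(gy, gx) %o% gz * peak
  vol[iy, ix, iz] <- vol[iy, ix, iz, drop = FALSE] + blob
  vol
}

#' Render the scene's emission intensity at one time point
#'
#' Voxelizes the scene at time `t`: each bead contributes an isotropic 3D
#' Gaussian blob (FWHM = bead diameter, peak = brightness scaled by the
#' instantaneous stimulus amplitude), plus the background field if present.
#'
#' @param scene a [scene_spec()]
#' @param t_ms time, ms, within `[0, duration]`
#' @param objects which objects to render (default all); `integer(0)` renders
#'   background only
#' @param with_background include the background field
#' @return 3D array `[y, x, z]` with attributes `z_planes` (um, 0 at
#'   mid-depth) and `pitch_um`
#' @export
render_intensity <- function(scene, t_ms, objects = NULL,
                             with_background = TRUE) {
  if (t_ms < 0 || t_ms > scene$duration_ms) {
    stop_invalid("`t_ms` outside the scene duration", "evlfm_out_of_range")
  }
  g <- scene_grid(scene)
  vol <- array(0, c(g$ny, g$nx, g$nz))
  idx <- objects %||% seq_along(scene$objects)
  for (i in idx) {
    ob <- scene$objects[[i]]
    amp <- stimulus_amplitude(ob$stimulus, t_ms)
    if (amp <= 0 || ob$brightness <= 0) next
    pos <- traj_position(ob$trajectory, t_ms)[1, ]
    vol <- stamp_bead(vol, g, pos, ob$radius_um, ob$brightness * amp,
                      scene$voxel_pitch_um)
  }
  if (with_background && !is.null(scene$background)) {
    bg <- realize_background(scene)
    vol <- vol + bg$field * background_gain(scene, t_ms)
  }
  structure(vol, z_planes = g$z_planes, pitch_um = scene$voxel_pitch_um)
}
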