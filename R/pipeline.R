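# end-to-end plumbing: scene -> sensor frames -> events -> frames -> volumes

#' Render the sensor-plane image sequence of a scene
#'
#' Projects the scene through the Fourier-LFM geometry at each requested time.
#' Static objects and the background are projected once and scaled by their
#' instantaneous stimulus amplitude / drift gain; moving objects are
#' re-rendered per time step. The scene's lateral voxel pitch must equal the
#' geometry's object-space sampling (`lateral_um_per_px`) and its lateral
#' extent must map onto `view_size` pixels.
#'
#' @param scene a [scene_spec()]
#' @param geometry a [system_geometry()]
#' @param times_ms sample times, ms
#' @return list with `frames` (list of sensor matrices) and `times_ms`
#' @export
render_sensor_sequence <- function(scene, geometry, times_ms) {
  render <- sensor_frame_renderer(scene, geometry)
  list(frames = lapply(times_ms, render), times_ms = times_ms)
}

#' Lazy sensor-frame renderer
#'
#' Returns a function `f(t_ms)` rendering the sensor-plane image of the
#' scene at time `t_ms`, with static-object and background projections
#' cached. Used by [simulate_recording()] to drive the event sensor without
#' holding the whole image sequence in memory.
#'
#' @inheritParams render_sensor_sequence
#' @return function of one time argument
#' @export
sensor_frame_renderer <- function(scene, geometry) {
  g <- scene_grid(scene)
  if (g$nx != geometry$view_size || g$ny != geometry$view_size) {
    stop_invalid(paste0(
      "scene lateral grid (", g$ny, "x", g$nx, ") must match the geometry ",
      "view size (", geometry$view_size, ")"))
  }
  static_idx <- which(vapply(scene$objects,
                             function(ob) traj_is_static(ob$trajectory),
                             logical(1)))
  moving_idx <- setdiff(seq_along(scene$objects), static_idx)

  # one tiled template per static object (unit stimulus amplitude)
  templates <- lapply(static_idx, function(i) {
    ob <- scene$objects[[i]]
    vol <- array(0, c(g$ny, g$nx, g$nz))
    pos <- traj_position(ob$trajectory, 0)[1, ]
    vol <- stamp_bead(vol, g, pos, ob$radius_um, ob$brightness,
                      scene$voxel_pitch_um)
    attr(vol, "z_planes") <- g$z_planes
    tile_views(project_views(vol, geometry), geometry)
  })
  bg_template <- NULL
  if (!is.null(scene$background)) {
    bg <- realize_background(scene)
    vol <- bg$field
    attr(vol, "z_planes") <- g$z_planes
    bg_template <- tile_views(project_views(vol, geometry), geometry)
  }

  function(t) {
    canvas <- matrix(0, geometry$sensor_shape[2], geometry$sensor_shape[1])
    for (j in seq_along(static_idx)) {
      ob <- scene$objects[[static_idx[j]]]
      amp <- stimulus_amplitude(ob$stimulus, t)
      if (amp > 0) canvas <- canvas + amp * templates[[j]]
    }
    if (length(moving_idx)) {
      vol <- render_intensity(scene, t, objects = moving_idx,
                              with_background = FALSE)
      if (any(vol != 0)) {
        canvas <- canvas + tile_views(project_views(vol, geometry), geometry)
      }
    }
    if (!is.null(bg_template)) {
      canvas <- canvas + bg_template * background_gain(scene, t)
    }
    canvas
  }
}

#' Simulate an event-camera recording of a scene
#'
#' Renders the scene through the optics at `dt_sample_ms` intervals (the
#' sampling must be at most half the accumulation window used downstream) and
#' converts the image sequence to an asynchronous event stream.
#'
#' @param scene a [scene_spec()]
#' @param geometry a [system_geometry()]
#' @param config a [sensor_config()]
#' @param dt_sample_ms optical sampling interval, ms
#' @param seed integer seed for the sensor
#' @return an [event_stream()]
#' @export
simulate_recording <- function(scene, geometry, config = sensor_config(),
                               dt_sample_ms = 0.25, seed = NULL) {
  times <- seq(0, scene$duration_ms, by = dt_sample_ms)
  render <- sensor_frame_renderer(scene, geometry)
  stream <- simulate_events(function(k) render(times[k]), times, config, seed)
  attr(stream, "meta")$scene_kind <- scene$meta$kind
  attr(stream, "meta")$geometry <- geometry
  stream
}

#' Reconstruct refocused volumes from an event stream
#'
#' The standard chain: time-surface frames at the accumulation window, view
#' cropping, shift-and-sum refocusing, optional median denoising and ghost
#' threshold cleanup.
#'
#' @param stream an [event_stream()]
#' @param geometry the [system_geometry()] of the recording
#' @param delta_ms accumulation window, ms
#' @param depths reconstruction depths, um
#' @param tau_ms time-surface decay, ms
#' @param polarity_mode time-surface polarity mode
#' @param denoise_kernel odd median kernel, or 0 to skip
#' @param clean_q ghost threshold as fraction of each volume's max, or 0
#' @param t_start_ms,t_end_ms span to reconstruct, ms
#' @return a [volume_sequence()]
#' @export
reconstruct_volumes <- function(stream, geometry, delta_ms, depths,
                                tau_ms = delta_ms / 3,
                                polarity_mode = "combined",
                                denoise_kernel = 0, clean_q = 0,
                                t_start_ms = NULL, t_end_ms = NULL) {
  fs <- frame_sequence(stream, delta_ms, t_start_ms, t_end_ms, tau_ms,
                       polarity_mode)
  centers <- calibrate_view_centers(geometry)
  vols <- lapply(fs$frames, function(fr) {
    if (denoise_kernel >= 3) fr <- denoise_frame(fr, denoise_kernel)
    views <- crop_views(fr, centers, geometry$lateral_um_per_px)
    vol <- refocus_volume(views, geometry$alpha, depths)
    if (clean_q > 0) vol <- threshold_clean(vol, clean_q)
    vol
  })
  volume_sequence(vols, fs$times_ms)
}
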