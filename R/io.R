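# I/O: TIFF export of frames/volumes/PSFs, YAML scene and geometry configs,
# CSV traces and tracks

#' Write a frame sequence as an 8-bit grayscale TIFF stack
#'
#' One page per frame; pixel values 0-255 map to the full 8-bit range.
#'
#' @param fs a `frame_sequence`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_frames_tiff <- function(fs, path) {
  pages <- lapply(fs$frames, function(f) unclass(f) / 255)
  tiff::writeTIFF(pages, path, bits.per.sample = 8)
  invisible(path)
}

#' Read an 8-bit TIFF stack back into a list of 0-255 matrices
#'
#' @param path input path
#' @return list of matrices
#' @export
read_frames_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  lapply(pages, function(p) round_half_up(p * 255))
}

#' Write a volume (or PSF array) as a 32-bit float multi-page TIFF
#'
#' One page per z-slice; intensities are normalized to the volume maximum
#' (the scale is returned invisibly). z-plane labels are written to a
#' `<path>.z.txt` sidecar.
#'
#' @param volume 3D array with a `z_planes` attribute
#' @param path output path
#' @return normalization scale, invisibly
#' @export
write_volume_tiff <- function(volume, path) {
  mx <- max(volume)
  scale <- if (mx > 0) mx else 1
  pages <- lapply(seq_len(dim(volume)[3]), function(k) volume[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32)
  zp <- attr(volume, "z_planes")
  if (!is.null(zp)) {
    writeLines(format(zp, scientific = FALSE), paste0(path, ".z.txt"))
  }
  invisible(scale)
}

# --- YAML configs -----------------------------------------------------------

traj_to_list <- function(tr) {
  out <- unclass(tr)
  if (!is.null(out$positions)) {
    out$positions <- apply(out$positions, 1, as.numeric, simplify = FALSE)
  }
  out
}

traj_from_list <- function(x) {
  if (x$type == "knots") {
    x$positions <- do.call(rbind, x$positions)
  }
  structure(x[setdiff(names(x), character(0))], class = "evlfm_traj")
}

#' Serialize a scene specification to YAML
#'
#' @param scene a [scene_spec()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_scene_yaml <- function(scene, path) {
  x <- list(
    extent_um = scene$extent_um, voxel_pitch_um = scene$voxel_pitch_um,
    duration_ms = scene$duration_ms, seed = scene$seed, meta = scene$meta,
    background = if (is.null(scene$background)) NULL
                 else unclass(scene$background),
    objects = lapply(scene$objects, function(ob) {
      list(radius_um = ob$radius_um, brightness = ob$brightness,
           trajectory = traj_to_list(ob$trajectory),
           stimulus = if (is.null(ob$stimulus)) NULL
                      else unclass(ob$stimulus))
    })
  )
  yaml::write_yaml(x, path)
  invisible(path)
}

#' Read a scene specification from YAML
#'
#' @param path input path
#' @return a [scene_spec()]
#' @export
read_scene_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  objects <- lapply(x$objects, function(ob) {
    stim <- if (is.null(ob$stimulus)) NULL else {
      stimulus_train(unlist(ob$stimulus$onsets), unlist(ob$stimulus$widths),
                     ob$stimulus$amplitude, ob$stimulus$flicker_hz,
                     ob$stimulus$flicker_depth)
    }
    bead_object(traj_from_list(ob$trajectory), ob$radius_um, ob$brightness,
                stim)
  })
  bg <- if (is.null(x$background)) NULL else {
    background_spec(x$background$mean_level, x$background$drift_timescale_ms,
                    x$background$spatial_corr_um)
  }
  scene_spec(objects, unlist(x$extent_um), unlist(x$voxel_pitch_um),
             x$duration_ms, background = bg, seed = x$seed,
             meta = x$meta %||% list())
}

#' Serialize a system geometry to YAML
#'
#' @param geometry a [system_geometry()]
#' @param path output path
#' @return `path`, invisibly
#' @export
write_geometry_yaml <- function(geometry, path) {
  yaml::write_yaml(unclass(geometry), path)
  invisible(path)
}

#' Read a system geometry from YAML
#'
#' @param path input path
#' @return a [system_geometry()]
#' @export
read_geometry_yaml <- function(path) {
  x <- yaml::read_yaml(path)
  system_geometry(x$grid_side, x$view_size, x$view_pitch,
                  unlist(x$sensor_shape), x$alpha, x$blur_sigma0, x$z_r,
                  unlist(x$z_range), x$pixel_pitch_um, x$lateral_um_per_px)
}

#' Write a trace as CSV (time, value)
#'
#' @param trace a `trace`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_trace_csv <- function(trace, path) {
  write.table(as.data.frame(trace), path, sep = ",", quote = FALSE,
              row.names = FALSE)
  invisible(path)
}

#' Write a track set as CSV (time, x, y, z, id)
#'
#' @param tracks a `track_set`
#' @param path output path
#' @return `path`, invisibly
#' @export
write_tracks_csv <- function(tracks, path) {
  write.table(as.data.frame(tracks)[, c("time_ms", "x_um", "y_um", "z_um", "id")],
              path, sep = ",", quote = FALSE, row.names = FALSE)
  invisible(path)
}
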