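# lfm_forward: project a 3D intensity grid through the Fourier-LFM geometry
# into a grid of sub-aperture views tiled onto the sensor plane

#' Fourier-LFM system geometry
#'
#' Describes the multi-view geometry: an odd `grid_side` x `grid_side` array
#' of sub-aperture views, the pixel pitch between view centers on the sensor,
#' a disparity slope `alpha` (lateral shift in view pixels per um of depth per
#' unit view index), and a defocus-like blur law
#' `sigma(z) = blur_sigma0 * sqrt(1 + (z / z_r)^2)`.
#'
#' @param grid_side number of views per side (odd; 5 in the reference system)
#' @param view_size side length of one view, px
#' @param view_pitch sensor pixels between adjacent view centers
#' @param sensor_shape c(width, height) of the sensor, px (IMX636-class
#'   default 1280 x 720)
#' @param alpha disparity slope, px/um per view index; the default caps the
#'   extreme-view shift over the axial range at 1/8 of a view tile
#' @param blur_sigma0 in-focus view-plane PSF sigma, px
#' @param z_r depth scale of defocus widening, um (default half the axial
#'   range)
#' @param z_range c(min, max) supported depths, um (0 = nominal focal plane)
#' @param pixel_pitch_um physical sensor pixel pitch, um
#' @param lateral_um_per_px object-space um per view pixel
#' @return an object of class `system_geometry`
#' @export
system_geometry <- function(grid_side = 5, view_size = 144,
                            view_pitch = view_size,
                            sensor_shape = NULL, alpha = NULL,
                            blur_sigma0 = 1, z_r = NULL,
                            z_range = c(-100, 100), pixel_pitch_um = 4.86,
                            lateral_um_per_px = 1) {
  if (grid_side %% 2 != 1 || grid_side < 1) {
    stop_invalid("`grid_side` must be odd and positive")
  }
  if (view_pitch < view_size) {
    stop_invalid("`view_pitch` must be at least `view_size`")
  }
  sensor_shape <- sensor_shape %||% rep(grid_side * view_pitch, 2L)
  if (grid_side * view_pitch > min(sensor_shape)) {
    stop_invalid("view grid does not fit inside `sensor_shape`")
  }
  hw <- (grid_side - 1) / 2
  zmax <- max(abs(z_range))
  alpha <- alpha %||% (if (hw > 0 && zmax > 0) view_size / (8 * hw * zmax) else 0)
  if (alpha < 0) stop_invalid("`alpha` must be >= 0")
  z_r <- z_r %||% (zmax / 2)
  structure(
    list(grid_side = as.integer(grid_side), view_size = as.integer(view_size),
         view_pitch = as.integer(view_pitch),
         sensor_shape = as.integer(sensor_shape), alpha = alpha,
         blur_sigma0 = blur_sigma0, z_r = z_r, z_range = as.numeric(z_range),
         pixel_pitch_um = pixel_pitch_um,
         lateral_um_per_px = lateral_um_per_px),
    class = "system_geometry"
  )
}

#' @export
print.system_geometry <- function(x, ...) {
  cat(sprintf(
    "<system_geometry> %dx%d views of %d px (pitch %d) on %dx%d sensor; alpha %.4g px/um; z in [%g, %g] um\n",
    x$grid_side, x$grid_side, x$view_size, x$view_pitch, x$sensor_shape[1],
    x$sensor_shape[2], x$alpha, x$z_range[1], x$z_range[2]))
  invisible(x)
}

#' Defocus blur width at depth z
#'
#' @param geometry a [system_geometry()]
#' @param z depth, um
#' @return sigma in view pixels
#' @export
blur_sigma <- function(geometry, z) {
  geometry$blur_sigma0 * sqrt(1 + (z / geometry$z_r)^2)
}

# centered view indices, e.g. -2..2 for a 5x5 grid
view_indices <- function(geometry) {
  hw <- (geometry$grid_side - 1L) %/% 2L
  (-hw):hw
}

# tile placement: top-left (1-based) row/col of each view tile on the sensor,
# with the s x s block centered on the canvas
view_tops <- function(geometry) {
  s <- geometry$grid_side; p <- geometry$view_pitch; vs <- geometry$view_size
  w <- geometry$sensor_shape[1]; h <- geometry$sensor_shape[2]
  top0 <- floor((h - s * p) / 2); left0 <- floor((w - s * p) / 2)
  off <- floor((p - vs) / 2)
  idx <- view_indices(geometry)
  grid <- expand.grid(v = idx, u = idx)
  tibble(
    u = grid$u, v = grid$v,
    row0 = top0 + (grid$v + max(idx)) * p + off + 1L,
    col0 = left0 + (grid$u + max(idx)) * p + off + 1L,
    row_c = top0 + (grid$v + max(idx)) * p + off + (vs + 1) / 2,
    col_c = left0 + (grid$u + max(idx)) * p + off + (vs + 1) / 2
  )
}

# --- view containers --------------------------------------------------------

# views: 4D array [y, x, v-index, u-index]; uv holds the centered indices
new_view_set <- function(arr, geometry) {
  structure(arr, uv = view_indices(geometry),
            lateral_um_per_px = geometry$lateral_um_per_px,
            class = "view_set")
}

#' Extract one sub-aperture view
#'
#' @param views a `view_set`
#' @param u,v centered view indices (0, 0 is the central view)
#' @return matrix
#' @export
get_view <- function(views, u, v) {
  uv <- attr(views, "uv")
  iu <- match(u, uv); iv <- match(v, uv)
  if (is.na(iu) || is.na(iv)) stop_invalid("view index outside the grid")
  views[, , iv, iu]
}

#' @export
print.view_set <- function(x, ...) {
  d <- dim(x)
  cat(sprintf("<view_set> %dx%d views of %dx%d px\n", d[4], d[3], d[1], d[2]))
  invisible(x)
}

n_views <- function(views) prod(dim(views)[3:4])

# --- forward projection -----------------------------------------------------

#' Project a volume into sub-aperture views
#'
#' View `(u, v)` is the depth sum of each z-slice laterally shifted by
#' `(u * alpha * z, v * alpha * z)` pixels and blurred by the depth-dependent
#' defocus kernel. The central view (0, 0) is the unshifted axial projection.
#'
#' @param volume 3D array `[y, x, z]` with a `z_planes` attribute (um); its
#'   lateral size must equal the geometry's `view_size`
#' @param geometry a [system_geometry()]
#' @param interp shift interpolation, `"bilinear"` (default) or `"nearest"`
#' @param blur apply the defocus blur (disable for shift-only energy checks)
#' @return a `view_set` (4D array `[y, x, v, u]`)
#' @export
project_views <- function(volume, geometry, interp = "bilinear", blur = TRUE) {
  d <- dim(volume)
  vs <- geometry$view_size
  if (d[1] != vs || d[2] != vs) {
    stop_invalid("volume lateral size does not match geometry `view_size`")
  }
  z_planes <- attr(volume, "z_planes")
  if (is.null(z_planes) || length(z_planes) != d[3]) {
    stop_invalid("volume must carry a `z_planes` attribute, one depth per slice")
  }
  idx <- view_indices(geometry)
  s <- geometry$grid_side
  out <- array(0, c(vs, vs, s, s))
  for (k in seq_len(d[3])) {
    slice <- volume[, , k]
    if (!any(slice != 0)) next
    z <- z_planes[k]
    if (blur) slice <- blur_gauss(slice, blur_sigma(geometry, z))
    for (a in seq_len(s)) {        # a: v index position
      for (b in seq_len(s)) {      # b: u index position
        dx <- idx[b] * geometry$alpha * z
        dy <- idx[a] * geometry$alpha * z
        out[, , a, b] <- out[, , a, b] + shift_image(slice, dx, dy, interp)
      }
    }
  }
  new_view_set(out, geometry)
}

#' Tile views onto the sensor canvas
#'
#' Places the views at centers spaced by `view_pitch` on a
#' `sensor_shape`-sized canvas; [untile_views()] inverts it exactly.
#'
#' @param views a `view_set`
#' @param geometry a [system_geometry()]
#' @return matrix of size `sensor_shape` (rows = height)
#' @export
tile_views <- function(views, geometry) {
  d <- dim(views)
  vs <- geometry$view_size
  if (d[1] != vs || d[2] != vs || d[3] != geometry$grid_side) {
    stop_invalid("views are inconsistent with the geometry")
  }
  if (vs > geometry$view_pitch) {
    stop_invalid("views exceed their allotted tile (overlap)")
  }
  canvas <- matrix(0, geometry$sensor_shape[2], geometry$sensor_shape[1])
  tops <- view_tops(geometry)
  idx <- view_indices(geometry)
  for (k in seq_len(nrow(tops))) {
    a <- match(tops$v[k], idx); b <- match(tops$u[k], idx)
    r <- tops$row0[k]; c <- tops$col0[k]
    canvas[r:(r + vs - 1), c:(c + vs - 1)] <- views[, , a, b]
  }
  canvas
}

#' Recover views from a tiled sensor image
#'
#' @param image sensor-shaped matrix
#' @param geometry a [system_geometry()]
#' @return a `view_set`
#' @export
untile_views <- function(image, geometry) {
  vs <- geometry$view_size; s <- geometry$grid_side
  if (nrow(image) != geometry$sensor_shape[2] ||
      ncol(image) != geometry$sensor_shape[1]) {
    stop_invalid("image does not match the geometry's sensor shape")
  }
  out <- array(0, c(vs, vs, s, s))
  tops <- view_tops(geometry)
  idx <- view_indices(geometry)
  for (k in seq_len(nrow(tops))) {
    a <- match(tops$v[k], idx); b <- match(tops$u[k], idx)
    r <- tops$row0[k]; c <- tops$col0[k]
    out[, , a, b] <- image[r:(r + vs - 1), c:(c + vs - 1)]
  }
  new_view_set(out, geometry)
}

#' Synthetic PSF stack of a point (or finite) source
#'
#' Projects a source at each depth through the geometry and tiles the views,
#' yielding one sensor image per depth (the direct-intensity analogue of the
#' translating-bead PSF acquisition). The default source is a unit point; a
#' view-sized matrix emulates a finite emitter (physical calibration beads
#' are not points).
#'
#' @param geometry a [system_geometry()]
#' @param depths depths, um, within the geometry `z_range`
#' @param source optional view-sized emitter image (default: centered delta)
#' @return a `psf_stack`: list of sensor images plus depth labels
#' @export
synth_psf_stack <- function(geometry, depths, source = NULL) {
  if (!length(depths)) stop_invalid("`depths` must be non-empty")
  if (any(depths < geometry$z_range[1] - 1e-9) ||
      any(depths > geometry$z_range[2] + 1e-9)) {
    stop_invalid("depths outside the geometry `z_range`")
  }
  vs <- geometry$view_size
  if (is.null(source)) {
    source <- matrix(0, vs, vs)
    source[floor(vs / 2) + 1L, floor(vs / 2) + 1L] <- 1
  }
  if (nrow(source) != vs || ncol(source) != vs) {
    stop_invalid("`source` must be a view-sized matrix")
  }
  images <- lapply(depths, function(z) {
    vol <- array(source, c(vs, vs, 1L))
    attr(vol, "z_planes") <- z
    tile_views(project_views(vol, geometry), geometry)
  })
  psf_stack(images, depths, geometry)
}

#' Gaussian bead emitter image
#'
#' View-sized image of an isotropic Gaussian bead (FWHM = diameter), the
#' finite-source input for [synth_psf_stack()].
#'
#' @param geometry a [system_geometry()]
#' @param radius_um bead radius, um
#' @return view-sized matrix, unit peak
#' @export
bead_source <- function(geometry, radius_um = 1) {
  vs <- geometry$view_size
  sig <- 2 * radius_um / (2 * sqrt(2 * log(2))) / geometry$lateral_um_per_px
  c0 <- floor(vs / 2) + 1L
  g <- exp(-((seq_len(vs)) - c0)^2 / (2 * sig^2))
  outer(g, g)
}

#' PSF stack container
#'
#' @param images list of sensor images, one per depth
#' @param depths_um strictly monotone depth labels, um
#' @param geometry the [system_geometry()] the stack belongs to
#' @return an object of class `psf_stack`
#' @export
psf_stack <- function(images, depths_um, geometry = NULL) {
  if (length(images) != length(depths_um)) {
    stop_invalid("one image per depth required")
  }
  if (length(depths_um) > 1 && any(diff(depths_um) <= 0)) {
    stop_invalid("depth labels must be strictly monotone")
  }
  structure(list(images = images, depths_um = as.numeric(depths_um),
                 geometry = geometry), class = "psf_stack")
}

#' @export
print.psf_stack <- function(x, ...) {
  cat(sprintf("<psf_stack> %d depths in [%g, %g] um\n", length(x$depths_um),
              min(x$depths_um), max(x$depths_um)))
  invisible(x)
}

#' Stack a PSF sequence into a 3D array
#'
#' @param psf a `psf_stack`
#' @param crop `"full"` keeps whole sensor images; `"central"` crops the
#'   central view tile (compact 3D PSF for MTF analysis)
#' @return 3D array `[y, x, z]` with a `z_planes` attribute
#' @export
as_psf_array <- function(psf, crop = c("full", "central")) {
  crop <- match.arg(crop)
  imgs <- psf$images
  if (crop == "central") {
    geom <- psf$geometry
    if (is.null(geom)) stop_invalid("central crop requires a geometry")
    tops <- view_tops(geom)
    k <- which(tops$u == 0 & tops$v == 0)
    vs <- geom$view_size
    r <- tops$row0[k]; c <- tops$col0[k]
    imgs <- lapply(imgs, function(im) im[r:(r + vs - 1), c:(c + vs - 1)])
  }
  arr <- array(unlist(imgs), c(dim(imgs[[1]]), length(imgs)))
  attr(arr, "z_planes") <- psf$depths_um
  arr
}
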