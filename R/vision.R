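# The simulated ant-eye visual system.
#
# A view from a pose is produced in three stages:
#   1. project_to_sphere(): move the world origin to the eye, convert patch
#      vertices to (azimuth, elevation) and discard radial distance;
#   2. rasterize_view(): paint the projected triangles into a binary
#      high-resolution raster (sky = 0, object = 1);
#   3. downsample_view(): block-average down to the 17 x 90 panorama, the
#      approximate sampling resolution of the ant compound eye, giving grey
#      values equal to the fraction of each block covered by objects.

PANO_ROWS <- 17L
PANO_COLS <- 90L

#' Agent pose
#'
#' @param x,y position (m).
#' @param heading viewing/travel direction, degrees clockwise from north
#'   (+y); normalised to [0, 360).
#' @param eye_height eye height above the ground plane (m).
#' @return an object of class `ant_pose`.
#' @export
pose <- function(x = 0, y = 0, heading = 0, eye_height = 0.01) {
  stopifnot(is.finite(x), is.finite(y), is.finite(heading), eye_height >= 0)
  structure(list(x = x, y = y, heading = wrap360(heading),
                 eye_height = eye_height),
            class = "ant_pose")
}

#' Project world patches onto the viewing sphere
#'
#' Translates patch vertices to an eye-centred frame and converts them to
#' (azimuth, elevation) in degrees; radial distance is discarded. Azimuth is
#' egocentric (relative to the pose heading, facing direction at 0) and each
#' triangle's vertex azimuths are unwrapped to be mutually continuous, so a
#' triangle straddling the +-180 degree seam occupies a single contiguous
#' azimuth interval (the rasterizer maps it back with modulo column
#' indexing). Patches with a vertex coincident with the eye point are
#' degenerate and are skipped with a warning.
#'
#' @param patches mesh matrix (n x 9) or an `ant_world`.
#' @param p an [pose()].
#' @return matrix (n x 6) of (az1, el1, az2, el2, az3, el3) in degrees.
#' @export
project_to_sphere <- function(patches, p) {
  if (inherits(patches, "ant_world")) {
    patches <- patches$patches
  }
  stopifnot(inherits(p, "ant_pose"), is.matrix(patches), ncol(patches) == 9)
  if (nrow(patches) == 0) {
    return(matrix(numeric(0), 0, 6))
  }
  sph <- cpp_project(patches, p$x, p$y, p$eye_height, p$heading)
  if (attr(sph, "skipped") > 0) {
    warning(attr(sph, "skipped"),
            " patch(es) coincident with the eye point skipped")
  }
  sph
}

#' Rasterize projected patches into a binary high-resolution view
#'
#' Pixels whose centre is covered by any projected triangle are set to 1
#' (object), all others stay 0 (sky). The raster spans 360 degrees of
#' azimuth (facing direction at the centre column) and `[0, el_span]`
#' degrees of elevation above the horizon; content below the horizon is
#' clipped, so objects appear purely as silhouettes against the sky. The
#' raster is `oversample` times finer than the 17 x 90 panorama in each
#' axis, so down-sampling is an exact block average.
#'
#' @param sph projected patches from [project_to_sphere()].
#' @param oversample integer raster refinement factor per axis; the default
#'   40 gives a 680 x 3600 raster (0.1 degrees per pixel).
#' @param el_span vertical field of view in degrees (17 rows x 4 degrees).
#' @return binary integer matrix, `17 * oversample` rows (row 1 at the
#'   horizon) by `90 * oversample` columns.
#' @export
rasterize_view <- function(sph, oversample = 40L, el_span = 68) {
  stopifnot(is.matrix(sph), ncol(sph) == 6,
            oversample == as.integer(oversample), oversample >= 1)
  cpp_rasterize(sph, PANO_ROWS * as.integer(oversample),
                PANO_COLS * as.integer(oversample), el_span)
}

#' Down-sample a high-resolution view to the 17 x 90 panorama
#'
#' Each panorama value is the arithmetic mean of its block of raster
#' pixels, i.e. the fraction of that block covered by objects; values lie
#' in `[0, 1]` and the global mean of the image is preserved exactly.
#'
#' @param h binary high-resolution view whose dimensions are multiples of
#'   (17, 90).
#' @return 17 x 90 numeric matrix (1530 values).
#' @export
downsample_view <- function(h) {
  stopifnot(is.matrix(h))
  if (nrow(h) %% PANO_ROWS != 0 || ncol(h) %% PANO_COLS != 0) {
    stop("high-resolution view dimensions must be multiples of (17, 90), got ",
         nrow(h), " x ", ncol(h))
  }
  if (!is.integer(h)) {
    storage.mode(h) <- "integer"
  }
  cpp_block_average(h, PANO_ROWS, PANO_COLS)
}

#' Render the panoramic view from a pose
#'
#' Convenience wrapper running projection, rasterization and down-sampling.
#' Rendering is a pure function of (world, pose, resolution).
#'
#' @inheritParams project_to_sphere
#' @inheritParams rasterize_view
#' @param world an `ant_world` (or bare mesh matrix).
#' @param highres also return the intermediate binary raster.
#' @return the 17 x 90 panorama matrix; if `highres = TRUE`, a list with
#'   elements `panorama` and `raster`.
#' @export
#' @examples
#' w <- build_world(world_config(region_size = 6, density = 0.3,
#'                               n_panorama = 8), seed = 7)
#' v <- render_view(w, pose(0, 0, heading = 0), oversample = 4)
#' dim(v)       # 17 x 90
#' range(v)     # within [0, 1]
render_view <- function(world, p, oversample = 40L, el_span = 68,
                        highres = FALSE) {
  sph <- project_to_sphere(world, p)
  h <- rasterize_view(sph, oversample = oversample, el_span = el_span)
  pano <- cpp_block_average(h, PANO_ROWS, PANO_COLS)
  if (highres) list(panorama = pano, raster = h) else pano
}

#' Rotate a panoramic view by a multiple of its column width
#'
#' Returns the view as it would appear after turning the viewer clockwise
#' by `delta` degrees: content shifts left by `delta / column width`
#' columns, circularly, with all values preserved. For the 90-column
#' panorama `delta` must be a multiple of 4 degrees; for a high-resolution
#' view, a multiple of its own column width. The equivalence
#' `rotate_view(render(pose), delta) == render(pose turned by delta)` is
#' exact, which is what makes column shifts usable as a visual compass.
#'
#' @param v panorama or high-resolution view matrix.
#' @param delta rotation in degrees (positive = clockwise).
#' @return matrix of the same dimensions.
#' @export
rotate_view <- function(v, delta) {
  stopifnot(is.matrix(v))
  colw <- 360 / ncol(v)
  s <- delta / colw
  if (abs(s - round(s)) > 1e-9) {
    stop("delta (", delta, " deg) is not a multiple of the column width (",
         colw, " deg)")
  }
  s <- round(s) %% ncol(v)
  if (s == 0) {
    return(v)
  }
  v[, c((s + 1):ncol(v), 1:s), drop = FALSE]
}

#' Proportion of sky visible in each direction
#'
#' Splits the view's columns into `n_directions` equal azimuthal sectors
#' and returns, for each, the mean of the sky indicator (1 - object) over
#' the sector's pixels -- effectively the inverse of the skyline height.
#' Directions are ordered left to right like the view columns, i.e. sector
#' centres run from -180 to +180 degrees relative to the heading the view
#' was rendered at.
#'
#' @param h a view matrix (high-resolution or panorama).
#' @param n_directions number of sectors; must divide the column count.
#' @return numeric vector of length `n_directions`, values in [0, 1].
#' @export
sky_profile <- function(h, n_directions = PANO_COLS) {
  stopifnot(is.matrix(h), ncol(h) %% n_directions == 0)
  per_col <- colMeans(h)
  grp <- (seq_along(per_col) - 1L) %/% (ncol(h) %/% n_directions)
  1 - as.numeric(rowsum(per_col, grp)) / (ncol(h) %/% n_directions)
}

# azimuth of the centre of each panorama column, relative to the heading
# the view was rendered at (degrees, left to right)
pano_col_centres <- function(n = PANO_COLS) {
  -180 + (seq_len(n) - 0.5) * 360 / n
}

#' @export
print.ant_pose <- function(x, ...) {
  cat(sprintf("<ant_pose> (%.3f, %.3f) m, heading %.1f deg, eye %.3f m\n",
              x$x, x$y, x$heading, x$eye_height))
  invisible(x)
}
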