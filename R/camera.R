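#' Camera model for the row-facing depth camera
#'
#' Bundles the optical and mounting constants needed to convert between
#' pixels, depth units and millimetres, and to build the tilted
#' depth-threshold plane. Defaults describe a 1280x720 stereo depth module
#' with an 87 x 58 degree field of view, mounted 1.22 m from the row centre
#' line and tilted 28.5 degrees up from the ground plane; raw depth units
#' are millimetres (`depth_scale = 0.001` m per unit).
#'
#' @param fov_x Horizontal field of view of the monochrome imager, degrees.
#' @param fov_y Vertical field of view, degrees.
#' @param tilt Camera tilt above the ground plane, degrees.
#' @param depth_scale Metres per raw depth unit.
#' @param frame_width,frame_height Frame size in pixels.
#' @param row_distance Perpendicular camera-to-row distance, metres.
#' @param bottom_plane_distance Threshold-plane distance at the bottom image
#'   row, metres. The default 1.23 m places the cut at the centre of the row.
#' @param top_plane_distance Optional override for the plane distance at the
#'   top image row, metres. When `NULL` (default) the top is computed from
#'   `fov_y` and `tilt`; when set, the plane is linearly interpolated
#'   between the two endpoints.
#'
#' @return An object of class `camera_model`.
#' @export
#' @examples
#' cam <- camera_model()
#' cam$fov_x
camera_model <- function(fov_x = 87, fov_y = 58, tilt = 28.5,
                         depth_scale = 0.001,
                         frame_width = 1280L, frame_height = 720L,
                         row_distance = 1.22,
                         bottom_plane_distance = 1.23,
                         top_plane_distance = NULL) {
  stopifnot(fov_x > 0, fov_x < 180, fov_y >= 0, fov_y < 180,
            depth_scale > 0, frame_width >= 1, frame_height >= 1,
            row_distance > 0, bottom_plane_distance > 0)
  if (!is.null(top_plane_distance)) stopifnot(top_plane_distance > 0)
  structure(list(fov_x = fov_x, fov_y = fov_y, tilt = tilt,
                 depth_scale = depth_scale,
                 frame_width = as.integer(frame_width),
                 frame_height = as.integer(frame_height),
                 row_distance = row_distance,
                 bottom_plane_distance = bottom_plane_distance,
                 top_plane_distance = top_plane_distance),
            class = "camera_model")
}

#' @export
print.camera_model <- function(x, ...) {
  cat("<camera_model> ", x$frame_width, "x", x$frame_height,
      " px, FOV ", x$fov_x, "° x ", x$fov_y, "°, tilt ",
      x$tilt, "°\n", sep = "")
  cat("  row distance ", x$row_distance, " m, bottom plane ",
      x$bottom_plane_distance, " m, depth scale ", x$depth_scale,
      " m/unit\n", sep = "")
  invisible(x)
}

deg2rad <- function(d) d * pi / 180

#' Tilted depth-threshold plane
#'
#' Computes the per-image-row distance cutoff that separates the harvested
#' row from the background. Because the camera is tilted upward, rays
#' through higher image rows travel farther before meeting the vertical
#' plane through the row, so the threshold grows from the bottom row to the
#' top row.
#'
#' The bottom-row hypotenuse is fixed at `bottom_plane_distance`. Rows are
#' assumed to sample the vertical row plane at equal height steps between
#' the bottom-ray and top-ray intersections (the per-pixel height in metres
#' is derived from `fov_y` and the perpendicular distance); each row's
#' threshold is the hypotenuse from the camera centre to that point. With
#' the default constants this puts the top row near 2.29 m. When the camera
#' tilt is less than half the vertical field of view, the lowest rays dip
#' below the horizontal and the raw hypotenuse has a sub-0.1 mm minimum a
#' few rows above the bottom; a running maximum taken from the bottom row
#' upward removes this so the plane is monotone.
#'
#' If `camera$top_plane_distance` is set, the plane is instead a linear
#' interpolation between the bottom and top distances.
#'
#' @param camera A [camera_model()].
#' @return Object of class `threshold_plane`: a list with `per_row_threshold`
#'   (numeric vector of metres, length `frame_height`, index 1 = top row).
#' @export
#' @examples
#' plane <- build_threshold_plane(camera_model())
#' range(plane$per_row_threshold)
build_threshold_plane <- function(camera) {
  stopifnot(inherits(camera, "camera_model"))
  h <- camera$frame_height
  rows <- seq_len(h)                      # 1 = top, h = bottom
  if (!is.null(camera$top_plane_distance)) {
    thr <- seq(camera$top_plane_distance, camera$bottom_plane_distance,
               length.out = h)
  } else if (h == 1L) {
    thr <- camera$bottom_plane_distance
  } else {
    theta_bot <- deg2rad(camera$tilt - camera$fov_y / 2)
    theta_top <- deg2rad(camera$tilt + camera$fov_y / 2)
    if (abs(theta_top) >= pi / 2)
      stop("camera geometry invalid: top ray parallel to the row plane")
    # bottom-row anchor point on the vertical row plane
    x0 <- camera$bottom_plane_distance * cos(theta_bot)   # perpendicular
    z0 <- camera$bottom_plane_distance * sin(theta_bot)   # height offset
    if (x0 <= 0) stop("camera geometry invalid: non-positive row distance")
    z_top <- x0 * tan(theta_top)
    # equal height steps up the plane, bottom row to top row
    z <- z0 + (z_top - z0) * (h - rows) / (h - 1)
    thr <- sqrt(x0^2 + z^2)
    # enforce monotone non-increasing top -> bottom
    thr <- rev(cummax(rev(thr)))
  }
  if (any(thr <= 0)) stop("camera geometry invalid: non-positive threshold")
  structure(list(per_row_threshold = thr), class = "threshold_plane")
}

#' Convert a bottom-row pixel width and depth into a stem diameter
#'
#' Applies the pixel-to-millimetre chain: the raw depth value is scaled to
#' millimetres, the half frame width at that distance follows from the
#' horizontal field of view, the mm-per-pixel ratio is that half width over
#' half the frame resolution, and the diameter is the pixel width times the
#' ratio.
#'
#' @param pixel_width Stem width on the bottom image row, pixels (>= 0).
#' @param depth_value Representative raw depth of the stem (>= 0).
#' @param camera A [camera_model()].
#' @return Object of class `tree_measurement`: list with `pixel_width`,
#'   `depth_value`, `distance_mm`, `half_frame_width_mm`, `ratio_mm_per_px`
#'   and `diameter_mm`.
#' @export
#' @examples
#' m <- diameter_from_width(20, 1230, camera_model())
#' m$diameter_mm
diameter_from_width <- function(pixel_width, depth_value, camera) {
  stopifnot(inherits(camera, "camera_model"),
            pixel_width >= 0, depth_value >= 0)
  distance_mm <- depth_value * camera$depth_scale * 1000
  half_frame_width_mm <- tan(deg2rad(camera$fov_x / 2)) * distance_mm
  ratio <- half_frame_width_mm / (camera$frame_width / 2)
  structure(list(pixel_width = pixel_width,
                 depth_value = depth_value,
                 distance_mm = distance_mm,
                 half_frame_width_mm = half_frame_width_mm,
                 ratio_mm_per_px = ratio,
                 diameter_mm = pixel_width * ratio),
            class = "tree_measurement")
}

#' Millimetres-per-pixel ratio at a given raw depth
#'
#' Convenience accessor for the scale factor used by [diameter_from_width()]
#' and by the synthetic scene generator when projecting a known diameter
#' into pixels.
#'
#' @inheritParams diameter_from_width
#' @return mm per pixel (numeric scalar).
#' @export
mm_per_pixel <- function(depth_value, camera) {
  diameter_from_width(0, depth_value, camera)$ratio_mm_per_px
}
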