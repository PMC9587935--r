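#' Rigid-body pose
#'
#' A timestamped rigid-body state: position in the world (motion-tracking)
#' frame plus a unit quaternion giving the body's orientation.
#'
#' @param t Time in seconds (finite, non-negative).
#' @param position Numeric 3-vector, meters, world frame.
#' @param orientation Unit quaternion `c(w, x, y, z)`; must have norm
#'   1 within `1e-9`.
#'
#' @return An object of class `"loc3d_pose"`: a list with elements `t`,
#'   `position` and `orientation`.
#' @export
#' @examples
#' pose(0, c(0, 0, 1.6), c(1, 0, 0, 0))
pose <- function(t, position, orientation = c(1, 0, 0, 0)) {
  if (!is.numeric(t) || length(t) != 1L || !is.finite(t) || t < 0)
    stop("`t` must be a single finite non-negative number", call. = FALSE)
  position <- as.numeric(position)
  orientation <- as.numeric(orientation)
  if (length(position) != 3L || any(!is.finite(position)))
    stop("`position` must be a finite 3-vector", call. = FALSE)
  check_quaternion(orientation)
  structure(list(t = t, position = position, orientation = orientation),
            class = "loc3d_pose")
}

check_quaternion <- function(q, tol = 1e-9) {
  if (length(q) != 4L || any(!is.finite(q)))
    stop("orientation must be a finite quaternion c(w, x, y, z)", call. = FALSE)
  n <- sqrt(sum(q^2))
  if (abs(n - 1) > tol)
    stop(sprintf("invalid pose: quaternion norm %.12f differs from 1", n),
         call. = FALSE)
  invisible(q)
}

#' @export
print.loc3d_pose <- function(x, ...) {
  cat(sprintf("<pose t=%.3f s  position=(%.3f, %.3f, %.3f) m  q=(%.4f, %.4f, %.4f, %.4f)>\n",
              x$t, x$position[1], x$position[2], x$position[3],
              x$orientation[1], x$orientation[2], x$orientation[3], x$orientation[4]))
  invisible(x)
}

#' Rotation matrix of a unit quaternion
#'
#' Converts a unit quaternion `c(w, x, y, z)` into the 3x3 rotation matrix
#' that maps body-frame vectors into the world frame.
#'
#' @param q Unit quaternion `c(w, x, y, z)`.
#' @return A 3x3 orthonormal rotation matrix.
#' @export
quat_to_rotmat <- function(q) {
  check_quaternion(q, tol = 1e-6)
  q <- q / sqrt(sum(q^2))
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  matrix(c(
    1 - 2 * (y^2 + z^2), 2 * (x * y - w * z), 2 * (x * z + w * y),
    2 * (x * y + w * z), 1 - 2 * (x^2 + z^2), 2 * (y * z - w * x),
    2 * (x * z - w * y), 2 * (y * z + w * x), 1 - 2 * (x^2 + y^2)
  ), nrow = 3, byrow = TRUE)
}

## quaternion for a yaw rotation about the vertical (z) axis; positive
## angle turns the forward axis (+y) toward the right (+x)
quat_yaw <- function(angle_deg) {
  half <- -angle_deg * pi / 360  # negative: +yaw is clockwise seen from above
  c(cos(half), 0, 0, sin(half))
}

#' Head-center calibration
#'
#' Computes the head-center position as the midpoint of the two ear
#' positions, the origin of the head-centered polar coordinate system.
#'
#' @param left_ear,right_ear Numeric 3-vectors, meters, world frame.
#' @return A list of class `"loc3d_head_calibration"` with elements
#'   `left_ear`, `right_ear` and `head_center` (the exact midpoint).
#' @export
#' @examples
#' calibrate_head_center(c(-0.075, 0, 0), c(0.075, 0, 0))$head_center
calibrate_head_center <- function(left_ear, right_ear) {
  left_ear <- as.numeric(left_ear)
  right_ear <- as.numeric(right_ear)
  if (length(left_ear) != 3L || length(right_ear) != 3L ||
      any(!is.finite(c(left_ear, right_ear))))
    stop("ear positions must be finite 3-vectors", call. = FALSE)
  structure(list(left_ear = left_ear, right_ear = right_ear,
                 head_center = (left_ear + right_ear) / 2),
            class = "loc3d_head_calibration")
}

#' World-to-head-frame re-referencing
#'
#' Expresses world-frame points relative to the head center, with the head's
#' straight-ahead direction mapped onto the head frame's forward (+y) axis.
#' The reference pose is the head pose captured at sound-delivery onset,
#' when the head is aligned straight ahead; `head_center_offset` is the fixed
#' body-frame translation from the tracked rigid-body origin to the calibrated
#' head center.
#'
#' @param point_world Numeric 3-vector or n x 3 matrix, meters, world frame.
#' @param reference_head A [pose()] (the straight-ahead-aligned head pose at
#'   delivery onset).
#' @param head_center_offset Body-frame 3-vector, meters, from rigid-body
#'   origin to head center (default `c(0, 0, 0)`).
#' @return Points in head-centered coordinates (same shape as the input).
#' @export
to_head_frame <- function(point_world, reference_head,
                          head_center_offset = c(0, 0, 0)) {
  R <- quat_to_rotmat(reference_head$orientation)
  center <- reference_head$position + as.numeric(R %*% head_center_offset)
  pts <- to_matrix3(point_world)
  out <- sweep(pts, 2, center) %*% R  # rows %*% R == t(R) %*% cols
  restore_shape(out, point_world)
}

#' @rdname to_head_frame
#' @param point_head Numeric 3-vector or n x 3 matrix in head-centered
#'   coordinates.
#' @export
from_head_frame <- function(point_head, reference_head,
                            head_center_offset = c(0, 0, 0)) {
  R <- quat_to_rotmat(reference_head$orientation)
  center <- reference_head$position + as.numeric(R %*% head_center_offset)
  pts <- to_matrix3(point_head)
  out <- sweep(pts %*% t(R), 2, center, `+`)
  restore_shape(out, point_head)
}

to_matrix3 <- function(p) {
  if (is.matrix(p)) {
    if (ncol(p) != 3L) stop("point matrix must have 3 columns", call. = FALSE)
    p
  } else {
    p <- as.numeric(p)
    if (length(p) != 3L) stop("point must be a 3-vector", call. = FALSE)
    matrix(p, nrow = 1)
  }
}

restore_shape <- function(out, original) {
  if (is.matrix(original)) out else as.numeric(out)
}

#' Cartesian / spherical conversion in the head frame
#'
#' Axis convention (right-handed): x = right, y = forward (straight ahead),
#' z = up. Azimuth is `atan2(x, y)` in degrees, signed positive rightward,
#' range (-180, 180]; elevation is the angle above the horizontal plane,
#' range \[-90, 90\]; depth is the Euclidean distance from the head center,
#' reported in centimeters. The zero vector is returned as a degenerate
#' coordinate (azimuth and elevation 0, `degenerate = TRUE`) rather than an
#' error.
#'
#' @param point_head Numeric 3-vector or n x 3 matrix, meters, head frame.
#' @return A data frame with columns `azimuth` (deg), `elevation` (deg),
#'   `depth_cm` and `degenerate` (logical).
#' @export
#' @examples
#' cartesian_to_spherical(c(0, 0.55, 0))  # straight ahead at 55 cm
cartesian_to_spherical <- function(point_head) {
  p <- to_matrix3(point_head)
  if (any(!is.finite(p))) stop("points must be finite", call. = FALSE)
  r <- sqrt(rowSums(p^2))
  degenerate <- r == 0
  az <- ifelse(degenerate, 0, atan2(p[, 1], p[, 2]) * 180 / pi)
  ## map the -180 branch onto +180 so azimuth lies in (-180, 180]
  az <- ifelse(az <= -180, az + 360, az)
  el <- ifelse(degenerate, 0, asin(pmin(1, pmax(-1, p[, 3] / ifelse(r == 0, 1, r)))) * 180 / pi)
  data.frame(azimuth = az, elevation = el, depth_cm = 100 * r,
             degenerate = degenerate)
}

#' @rdname cartesian_to_spherical
#' @param azimuth,elevation Angles in degrees.
#' @param depth_cm Radial distance in centimeters (>= 0).
#' @export
spherical_to_cartesian <- function(azimuth, elevation, depth_cm) {
  if (any(depth_cm < 0)) stop("depth must be non-negative", call. = FALSE)
  az <- azimuth * pi / 180
  el <- elevation * pi / 180
  r <- depth_cm / 100
  out <- cbind(x = r * cos(el) * sin(az),
               y = r * cos(el) * cos(az),
               z = r * sin(el))
  if (length(azimuth) == 1L) as.numeric(out) else unname(out)
}

#' The 12 predetermined target positions
#'
#' The experimental grid: four azimuths (-150, -30, +30, +150 degrees) x
#' three depths (35, 55, 75 cm) at ear-level elevation (0 degrees). The
#' antero-posterior `sector` is front when |azimuth| < 90, back otherwise;
#' `distance` labels the depths near/middle/far.
#'
#' @return A 12-row data frame with columns `azimuth`, `elevation`,
#'   `depth_cm`, `sector`, `distance` and head-frame Cartesian coordinates
#'   `x`, `y`, `z` (meters).
#' @export
target_grid <- function() {
  g <- expand.grid(azimuth = c(-150, -30, 30, 150),
                   depth_cm = c(35, 55, 75))
  g$elevation <- 0
  g$sector <- ifelse(abs(g$azimuth) < 90, "front", "back")
  g$distance <- c("near", "middle", "far")[match(g$depth_cm, c(35, 55, 75))]
  xyz <- spherical_to_cartesian(g$azimuth, g$elevation, g$depth_cm)
  g$x <- xyz[, 1]; g$y <- xyz[, 2]; g$z <- xyz[, 3]
  g[order(g$azimuth, g$depth_cm), c("azimuth", "elevation", "depth_cm",
                                    "sector", "distance", "x", "y", "z")]
}

## facing azimuth (deg) of a head orientation relative to the reference pose:
## forward body axis (0,1,0) rotated into the world, then re-expressed in the
## reference head frame
head_facing_azimuth <- function(q, reference_head) {
  Rref <- quat_to_rotmat(reference_head$orientation)
  fwd <- quat_to_rotmat(q) %*% c(0, 1, 0)
  f <- as.numeric(t(Rref) %*% fwd)
  atan2(f[1], f[2]) * 180 / pi
}
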