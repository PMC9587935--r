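#' Sound-delivery gating criteria
#'
#' The trial controller delivered the sound only when three criteria held
#' concurrently: (1) the loudspeaker was inside a tolerance sphere around its
#' predetermined head-centered position (radius 2.5 cm), (2) the head faced
#' straight ahead, (3) the eyes were directed straight ahead. The angular
#' tolerances for head and eye alignment are configuration choices (the
#' crosshair-alignment task does not fix them); the defaults are 5 degrees.
#'
#' @param placement_tolerance_cm Radius of the speaker tolerance sphere, cm.
#' @param head_tolerance_deg Maximum head deviation from straight ahead, deg.
#' @param eye_tolerance_deg Maximum gaze deviation from straight ahead, deg.
#' @return A list of class `"loc3d_gating_criteria"`.
#' @export
gating_criteria <- function(placement_tolerance_cm = 2.5,
                            head_tolerance_deg = 5,
                            eye_tolerance_deg = 5) {
  vals <- c(placement_tolerance_cm, head_tolerance_deg, eye_tolerance_deg)
  if (any(!is.finite(vals)) || any(vals <= 0))
    stop("all gating tolerances must be positive", call. = FALSE)
  structure(list(placement_tolerance_cm = placement_tolerance_cm,
                 head_tolerance_deg = head_tolerance_deg,
                 eye_tolerance_deg = eye_tolerance_deg),
            class = "loc3d_gating_criteria")
}

angle_between_deg <- function(a, b) {
  d <- sum(a * b) / (sqrt(sum(a^2)) * sqrt(sum(b^2)))
  acos(pmin(1, pmax(-1, d))) * 180 / pi
}

#' Sound-delivery decision
#'
#' Offline re-implementation of the delivery gate: checks the three criteria
#' for a single instant. Positions are in a common frame with distances in
#' meters; the tolerance boundary is inclusive (the tolerance region is a
#' closed ball / closed cone).
#'
#' @param speaker_pos,target_pos 3-vectors, meters: actual speaker position
#'   and predetermined target position.
#' @param head_dir,eye_dir Unit 3-vectors (within `1e-6`): current head facing
#'   and cyclopean gaze directions.
#' @param criteria A [gating_criteria()] object.
#' @param reference_dir Unit 3-vector: the recorded straight-ahead reference
#'   direction (default: the world forward axis `c(0, 1, 0)`).
#' @return A list of class `"loc3d_gating_decision"` with elements `deliver`
#'   (logical), `failed_criteria` (character subset of
#'   `c("placement", "head", "eye")`), `placement_error_3d` (cm),
#'   `head_deviation` and `eye_deviation` (degrees).
#' @export
#' @examples
#' check_delivery(c(0, 0.55, 0), c(0, 0.55, 0), c(0, 1, 0), c(0, 1, 0))
check_delivery <- function(speaker_pos, target_pos, head_dir, eye_dir,
                           criteria = gating_criteria(),
                           reference_dir = c(0, 1, 0)) {
  stopifnot(inherits(criteria, "loc3d_gating_criteria"))
  for (d in list(head_dir, eye_dir, reference_dir)) {
    if (length(d) != 3L || any(!is.finite(d)))
      stop("direction vectors must be finite 3-vectors", call. = FALSE)
    if (abs(sqrt(sum(d^2)) - 1) > 1e-6)
      stop("direction vectors must be unit-norm within 1e-6", call. = FALSE)
  }
  placement_error <- 100 * sqrt(sum((as.numeric(speaker_pos) -
                                       as.numeric(target_pos))^2))
  head_dev <- angle_between_deg(head_dir, reference_dir)
  eye_dev <- angle_between_deg(eye_dir, reference_dir)
  failed <- c(
    if (placement_error > criteria$placement_tolerance_cm) "placement",
    if (head_dev > criteria$head_tolerance_deg) "head",
    if (eye_dev > criteria$eye_tolerance_deg) "eye"
  )
  structure(list(deliver = length(failed) == 0L,
                 failed_criteria = as.character(failed),
                 placement_error_3d = placement_error,
                 head_deviation = head_dev,
                 eye_deviation = eye_dev),
            class = "loc3d_gating_decision")
}

#' Locate the sound-delivery onset in a trial's tracks
#'
#' Scans the head-track sampling grid for the earliest sample at which all
#' three gating criteria pass; that time defines t = 0 of the sound window
#' and the kinematic reference pose. Eye and speaker samples are aligned to
#' the head grid by sample-and-hold (previous-value) interpolation, matching
#' how a slower tracker's last sample is the one a real-time controller sees.
#' Delivery is triggered on the first passing sample (no sustained-hold
#' requirement).
#'
#' @param head Data frame with columns `t`, `x`, `y`, `z`, `qw`, `qx`, `qy`,
#'   `qz`: head rigid-body track (world frame, meters/seconds).
#' @param eye Data frame with columns `t`, `x`, `y`, `z`: unit gaze direction.
#' @param speaker Data frame with columns `t`, `x`, `y`, `z`: speaker position.
#' @param target_world 3-vector, meters: predetermined speaker position in the
#'   world frame.
#' @param criteria A [gating_criteria()] object.
#' @param reference_dir Straight-ahead reference direction (unit 3-vector).
#' @return The onset time in seconds (a value of the head-track grid).
#' @export
find_delivery_onset <- function(head, eye, speaker, target_world,
                                criteria = gating_criteria(),
                                reference_dir = c(0, 1, 0)) {
  stopifnot(is.data.frame(head), is.data.frame(eye), is.data.frame(speaker))
  t <- head$t
  hold <- function(track, col)
    stats::approx(track$t, track[[col]], xout = t, method = "constant",
                  f = 0, rule = 2)$y
  sx <- hold(speaker, "x"); sy <- hold(speaker, "y"); sz <- hold(speaker, "z")
  ex <- hold(eye, "x"); ey <- hold(eye, "y"); ez <- hold(eye, "z")
  en <- sqrt(ex^2 + ey^2 + ez^2)
  ex <- ex / en; ey <- ey / en; ez <- ez / en

  placement_cm <- 100 * sqrt((sx - target_world[1])^2 +
                               (sy - target_world[2])^2 +
                               (sz - target_world[3])^2)
  ## head forward axis per sample from the quaternion columns
  fx <- 2 * (head$qx * head$qy - head$qw * head$qz)
  fy <- 1 - 2 * (head$qx^2 + head$qz^2)
  fz <- 2 * (head$qy * head$qz + head$qw * head$qx)
  r <- reference_dir / sqrt(sum(reference_dir^2))
  head_dev <- acos(pmin(1, pmax(-1, fx * r[1] + fy * r[2] + fz * r[3]))) * 180 / pi
  eye_dev <- acos(pmin(1, pmax(-1, ex * r[1] + ey * r[2] + ez * r[3]))) * 180 / pi

  ok <- placement_cm <= criteria$placement_tolerance_cm &
    head_dev <= criteria$head_tolerance_deg &
    eye_dev <= criteria$eye_tolerance_deg
  if (!any(ok))
    stop("no-delivery: gating criteria are never concurrently met", call. = FALSE)
  t[which(ok)[1L]]
}
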