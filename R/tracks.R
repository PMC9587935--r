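## Synthesis of world-frame motion tracks for one trial (track_mode "full").
## Head reorientations are minimum-jerk yaw profiles about the head center;
## the tracked HMD marker rides a `head_pivot_m` lever arm, which converts
## angular motion into the translational speeds the 80 mm/s detector sees.
## The gaze track aligns exactly at t = 0 (a saccade onto the fixation
## cross), making the delivery gate open at t = 0 by construction.

## slow postural jitter: sum of three sub-Hz sinusoids per axis
make_jitter <- function(t, amp) {
  if (amp <= 0) return(numeric(length(t)))
  f <- stats::runif(3, 0.1, 0.45)
  a <- amp * stats::runif(3, 0.5, 1) / 3
  ph <- stats::runif(3, 0, 2 * pi)
  a[1] * sin(2 * pi * f[1] * t + ph[1]) +
    a[2] * sin(2 * pi * f[2] * t + ph[2]) +
    a[3] * sin(2 * pi * f[3] * t + ph[3])
}

## piecewise minimum-jerk position profile from p0 to p1 over [t0, t0 + dur]
mj_segment <- function(t, t0, dur, p0, p1) {
  s <- min_jerk((t - t0) / dur)
  outer(1 - s, p0) + outer(s, p1)
}

build_trial_tracks <- function(tr, movements, config) {
  dt <- 1 / config$sample_rate
  pivot <- config$head_pivot_m
  jit_m <- config$track_jitter_mm / 1000
  t_end <- tr$hand_onset_s + 0.95
  k <- seq.int(-ceiling(0.6 / dt), ceiling(t_end / dt))
  t <- k * dt

  ref_pose <- pose(0, c(tr$ref_x, tr$ref_y, tr$ref_z),
                   c(tr$ref_qw, tr$ref_qx, tr$ref_qy, tr$ref_qz))
  Rref <- quat_to_rotmat(ref_pose$orientation)
  yaw0 <- atan2(-2 * tr$ref_qw * tr$ref_qz, 1 - 2 * tr$ref_qz^2) * 180 / pi
  center0 <- ref_pose$position + as.numeric(Rref %*% c(0, -pivot, 0))

  ## --- head: yaw profile + marker on the pivot lever arm -----------------
  yaw <- rep(yaw0, length(t))
  if (!is.null(movements))
    for (j in seq_len(nrow(movements)))
      yaw <- yaw + movements$delta[j] *
        min_jerk((t - movements$onset[j]) / movements$duration[j])
  yaw <- yaw + 0.15 * config$track_jitter_mm * make_jitter(t, 1)
  cx <- center0[1] + make_jitter(t, jit_m)
  cy <- center0[2] + make_jitter(t, jit_m)
  cz <- center0[3] + make_jitter(t, jit_m)
  half <- -yaw * pi / 360
  qw <- cos(half); qz <- sin(half)
  ## marker = center + R(yaw) %*% (0, pivot, 0)
  yaw_r <- yaw * pi / 180
  head <- data.frame(t = t,
                     x = cx + pivot * sin(yaw_r),
                     y = cy + pivot * cos(yaw_r),
                     z = cz,
                     qw = qw, qx = 0, qy = 0, qz = qz)

  ## --- eye: 60 Hz gaze direction, aligned from t = 0 ---------------------
  ke <- seq.int(-ceiling(0.6 * config$eye_rate), ceiling(t_end * config$eye_rate))
  te <- ke / config$eye_rate
  off <- 10 * pi / 180
  eye <- data.frame(t = te,
                    x = ifelse(te < 0, sin(off), 0),
                    y = ifelse(te < 0, cos(off), 1),
                    z = 0)

  ## --- speaker: guided approach, hold through the sound, removal ---------
  aw <- c(tr$act_x, tr$act_y, tr$act_z)
  u <- stats::rnorm(3); u <- u / sqrt(sum(u^2))
  start <- aw + 0.3 * u
  sp <- matrix(rep(aw, each = length(t)), ncol = 3)
  pre <- t < -0.15
  sp[pre, ] <- mj_segment(t[pre], -0.55, 0.4, start, aw)
  post <- t > 3.05
  if (any(post)) sp[post, ] <- mj_segment(t[post], 3.05, 0.5, aw, aw + 0.6 * u)
  speaker <- data.frame(t = t, x = sp[, 1], y = sp[, 2], z = sp[, 3])

  ## --- hand: rest, then a minimum-jerk reach to the response point --------
  rest <- center0 + as.numeric(Rref %*% c(0.25, 0.15, -0.35))
  resp_world <- from_head_frame(c(tr$rx, tr$ry, tr$rz), ref_pose,
                                c(0, -pivot, 0))
  hp <- mj_segment(t, tr$hand_onset_s, 0.7, rest, resp_world)
  hand <- data.frame(t = t,
                     x = hp[, 1] + make_jitter(t, jit_m),
                     y = hp[, 2] + make_jitter(t, jit_m),
                     z = hp[, 3] + make_jitter(t, jit_m))

  list(head = head, eye = eye, hand = hand, speaker = speaker)
}
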