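#' Response-model parameters of the synthetic generator
#'
#' Pointing biases and dispersions per dimension x antero-posterior sector x
#' listening condition. The defaults are calibrated (folded-normal inversion
#' for the absolute errors, additive decomposition for the variable errors)
#' so that the expected group-level error statistics of a default cohort
#' match the behavioural regime the generator emulates: azimuth and
#' elevation improve with active listening mainly in front space, depth does
#' not depend on listening condition but shows distance-dependent bias
#' (overshoot of near, undershoot of far targets).
#'
#' Angular biases are eccentric (applied away from the midline with the sign
#' of the target azimuth); elevation bias is upward; depth bias depends on
#' the nominal distance. `tau_*` are between-participant dispersions of the
#' biases; `tau_cell_deg` adds participant x condition x sector jitter.
#'
#' @param angular Data frame with columns `dimension` (azimuth/elevation),
#'   `sector`, `bias_static`, `bias_active`, `sd_static`, `sd_active`
#'   (degrees).
#' @param depth_bias_cm Named vector, signed depth bias per distance, cm.
#' @param depth_sd_cm Named vector, trial-level depth SD per sector, cm.
#' @param tau_bias_deg,tau_cell_deg,tau_depth_cm Between-participant SDs.
#' @param angular_depth_scaling Scale angular biases and SDs inversely with
#'   target depth (normalized so the mean over the three depths is 1). This
#'   emulates pointing noise that is roughly constant in Cartesian space -
#'   the same hand displacement subtends a larger angle at a near target -
#'   and keeps the angular error statistics consistent with the composite
#'   3D (cm) error.
#' @return A list of class `"loc3d_response_params"`.
#' @export
loc3d_response_params <- function(
    angular = data.frame(
      dimension = c("azimuth", "azimuth", "elevation", "elevation"),
      sector = c("front", "back", "front", "back"),
      bias_static = c(25.7, 10.4, 26.6, 11.6),
      bias_active = c(14.5, 12.1, 18.4, 15.1),
      sd_static = c(11.7, 16.9, 26.0, 19.0),
      sd_active = c(9.1, 14.3, 16.0, 16.4)),
    depth_bias_cm = c(near = 4.4, middle = 5.2, far = -8.6),
    depth_sd_cm = c(front = 8.5, back = 11),
    tau_bias_deg = 7, tau_cell_deg = 4, tau_depth_cm = 3,
    angular_depth_scaling = TRUE) {
  stopifnot(all(c("dimension", "sector", "bias_static", "bias_active",
                  "sd_static", "sd_active") %in% names(angular)),
            nrow(angular) == 4L,
            all(angular$sd_static >= 0), all(angular$sd_active >= 0),
            tau_bias_deg >= 0, tau_cell_deg >= 0, tau_depth_cm >= 0)
  structure(list(angular = angular, depth_bias_cm = depth_bias_cm,
                 depth_sd_cm = depth_sd_cm, tau_bias_deg = tau_bias_deg,
                 tau_cell_deg = tau_cell_deg, tau_depth_cm = tau_depth_cm,
                 angular_depth_scaling = angular_depth_scaling),
            class = "loc3d_response_params")
}

#' Head-movement model parameters of the synthetic generator
#'
#' Spontaneous head reorientations during active listening: each
#' participant's propensity to move is Beta-distributed; moving trials carry
#' one or more minimum-jerk yaw reorientations with realistic onset latency.
#' First movements aim at the target in front space; for back targets they
#' mix full turns toward the target with partial turns into the front
#' quadrant of the target's side. The participant-level localization benefit
#' of active listening is coupled to the movement propensity (factor
#' `p_move / p_move_mean` plus jitter), so that cohorts exhibit a positive
#' rank correlation between head-movement rate and improvement.
#'
#' @param p_move_mean,p_move_sd Mean/SD of the per-participant probability of
#'   moving the head on an active trial.
#' @param extra_movement_rate Poisson rate of additional movements beyond the
#'   first on a moving trial.
#' @param onset_mean_ms,onset_between_sd_ms,onset_within_sd_ms First-movement
#'   onset latency: population mean, between- and within-participant SD.
#' @param benefit_coupling_sd SD of the jitter on the participant improvement
#'   factor.
#' @param front_gain_mean,front_gain_sd,front_dir_sd_deg Aiming gain and
#'   dispersion for front-target reorientations.
#' @param back_full_turn_prob,back_full_mean_deg,back_full_sd_deg,back_quad_mean_deg,back_quad_sd_deg
#'   Mixture model for back-target reorientations.
#' @return A list of class `"loc3d_movement_params"`.
#' @export
loc3d_movement_params <- function(
    p_move_mean = 0.736, p_move_sd = 0.24,
    extra_movement_rate = 0.22,
    onset_mean_ms = 1077, onset_between_sd_ms = 250, onset_within_sd_ms = 150,
    benefit_coupling_sd = 0.3,
    front_gain_mean = 0.85, front_gain_sd = 0.05, front_dir_sd_deg = 8,
    back_full_turn_prob = 0.65, back_full_mean_deg = 135,
    back_full_sd_deg = 12, back_quad_mean_deg = 55, back_quad_sd_deg = 15) {
  stopifnot(p_move_mean > 0, p_move_mean < 1, p_move_sd >= 0,
            extra_movement_rate >= 0, onset_mean_ms > 0,
            back_full_turn_prob >= 0, back_full_turn_prob <= 1)
  structure(as.list(environment()), class = "loc3d_movement_params")
}

#' Synthetic-experiment configuration
#'
#' Describes one synthetic experiment with the study design: 12 predetermined
#' head-centered positions (azimuth +-30/+-150 deg x depth 35/55/75 cm at
#' ear level), two listening conditions in ABBA-counterbalanced blocks of 48
#' randomized trials (8 trials per position per condition, 192 per
#' participant), speaker placement inside the 2.5 cm tolerance sphere,
#' condition-dependent response bias and dispersion, spontaneous head
#' reorientations in active listening, and a configurable rate of
#' anticipatory (rejectable) responses.
#'
#' `track_mode = "none"` emits trial-level data (responses plus kinematic
#' annotations); `"full"` additionally synthesizes 100 Hz world-frame head,
#' hand and speaker tracks and a 60 Hz gaze track for every trial, suitable
#' for the complete gating + kinematic pipeline.
#'
#' @param n_participants Number of virtual participants.
#' @param trials_per_cell Trials per position x condition cell (default 8).
#' @param seed Integer seed; all stochastic draws flow from it.
#' @param track_mode `"none"` or `"full"`.
#' @param noise_scale Multiplier on every random dispersion (0 gives
#'   deterministic responses).
#' @param bias_scale Multiplier on every systematic bias.
#' @param placement_scale Multiplier on the speaker-placement error.
#' @param response_params A [loc3d_response_params()] object.
#' @param movement_params A [loc3d_movement_params()] object.
#' @param anticipatory_rate Named vector: probability of an anticipatory hand
#'   response per condition.
#' @param static_head_move_rate Probability of a (rejectable) head movement
#'   during sound delivery in a static trial.
#' @param hand_rt_mean_s,hand_rt_between_sd_s,hand_rt_within_sd_s Hand
#'   response-onset model, seconds from sound onset (compliant responses
#'   start after the 3 s sound offset).
#' @param placement_tolerance_cm Gating tolerance sphere radius, cm.
#' @param placement_direction_sd Anisotropic (x, y, z) SDs shaping the
#'   placement-error direction.
#' @param placement_radius_beta Beta(a, b) parameters of the placement-error
#'   radius as a fraction of the tolerance radius (boundary-hugging law:
#'   guidance stops once the speaker enters the tolerance sphere).
#' @param sample_rate,eye_rate Track sampling rates, Hz.
#' @param head_pivot_m Distance from head center to the tracked HMD marker.
#' @param track_jitter_mm Amplitude of slow postural jitter in full tracks.
#' @param head_base_sd_m Between-trial SD of the initial head-center
#'   position (world frame).
#' @return A validated list of class `"loc3d_config"`.
#' @export
loc3d_config <- function(n_participants = 20, trials_per_cell = 8, seed = 1,
                         track_mode = c("none", "full"),
                         noise_scale = 1, bias_scale = 1, placement_scale = 1,
                         response_params = loc3d_response_params(),
                         movement_params = loc3d_movement_params(),
                         anticipatory_rate = c(static = 0.056, active = 0.066),
                         static_head_move_rate = 0.005,
                         hand_rt_mean_s = 3.65, hand_rt_between_sd_s = 0.30,
                         hand_rt_within_sd_s = 0.25,
                         placement_tolerance_cm = 2.5,
                         placement_direction_sd = c(0.8, 1.2, 0.9),
                         placement_radius_beta = c(6.0, 1.576),
                         sample_rate = 100, eye_rate = 60,
                         head_pivot_m = 0.10, track_jitter_mm = 2,
                         head_base_sd_m = 0.02) {
  track_mode <- match.arg(track_mode)
  stopifnot(n_participants >= 1, trials_per_cell >= 1,
            inherits(response_params, "loc3d_response_params"),
            inherits(movement_params, "loc3d_movement_params"),
            noise_scale >= 0, bias_scale >= 0, placement_scale >= 0,
            static_head_move_rate >= 0, static_head_move_rate <= 1,
            placement_tolerance_cm > 0, sample_rate > 0, eye_rate > 0)
  if (any(anticipatory_rate < 0) || any(anticipatory_rate > 1))
    stop("anticipatory_rate must lie in [0, 1]", call. = FALSE)
  if (!all(c("static", "active") %in% names(anticipatory_rate)))
    stop("anticipatory_rate needs named entries for static and active",
         call. = FALSE)
  structure(as.list(environment()), class = "loc3d_config")
}

min_jerk <- function(tau) {
  tau <- pmin(1, pmax(0, tau))
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

## duration (s) of a reorientation of |delta| degrees
yaw_duration <- function(delta_deg) 0.3 + 0.25 * abs(delta_deg) / 90

## truncated normal by rejection-free clamping (adequate for mild truncation)
rnorm_trunc <- function(n, mean, sd, lower, upper)
  pmin(upper, pmax(lower, stats::rnorm(n, mean, sd)))

#' Generate a complete synthetic experiment
#'
#' Draws a full cohort under the configured design. Every stochastic draw
#' flows from `config$seed` (the caller's RNG state is preserved), so the
#' same configuration reproduces byte-identical output.
#'
#' @param config A [loc3d_config()] object.
#' @return A list of class `"loc3d_cohort"`:
#'   \describe{
#'     \item{trials}{trial table: design columns (`participant`, `trial`,
#'       `block`, `condition`, nominal position and sector/distance labels),
#'       predetermined and actual speaker positions in head-centered meters
#'       (`ph_*`, `ah_*`) and world meters (`pre_*`, `act_*`), the
#'       delivery-onset reference pose (`ref_*`), the head-frame hand
#'       response (`rx`, `ry`, `rz`) and kinematic annotations
#'       (`n_head_movements`, `first_onset_s`, `first_end_azimuth`,
#'       `hand_onset_s`).}
#'     \item{ground_truth}{one row per trial with every injected parameter
#'       and label (effective biases/SDs, movement counts and onsets,
#'       compliance labels) for parameter-recovery tests.}
#'     \item{participants}{per-participant latent values (movement
#'       propensity, improvement factor, bias offsets).}
#'     \item{movements}{per-trial data frames of injected head
#'       reorientations (onset, amplitude, duration).}
#'     \item{tracks}{`NULL`, or (track_mode `"full"`) per-trial lists of
#'       `head`, `eye`, `hand`, `speaker` data frames in the long-track
#'       schema units (world meters/seconds).}
#'   }
#' @export
generate_experiment <- function(config = loc3d_config()) {
  stopifnot(inherits(config, "loc3d_config"))
  old_seed <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv()) else NULL
  on.exit(if (!is.null(old_seed)) assign(".Random.seed", old_seed, globalenv()))
  set.seed(config$seed)

  rp <- config$response_params
  mp <- config$movement_params
  ns <- config$noise_scale
  bs <- config$bias_scale
  grid <- target_grid()

  participants <- draw_participants(config)
  trial_list <- vector("list", config$n_participants)
  gt_list <- vector("list", config$n_participants)
  mov_list <- list()
  track_list <- if (config$track_mode == "full") list() else NULL

  for (i in seq_len(config$n_participants)) {
    pp <- participants[i, ]
    tt <- draw_trial_design(config, pp, grid)
    n <- nrow(tt)

    ## --- speaker placement: predetermined + boundary-hugging noise ------
    noise_cm <- draw_placement_noise(n, config) * config$placement_scale
    ph <- as.matrix(grid[match(paste(tt$position_az, tt$position_depth_cm),
                               paste(grid$azimuth, grid$depth_cm)),
                         c("x", "y", "z")])
    ah <- ph + noise_cm / 100
    act_sph <- cartesian_to_spherical(ah)

    ## --- head-movement model -------------------------------------------
    active <- tt$condition == "active"
    moved <- active & stats::runif(n) < pp$p_move
    static_viol <- !active & stats::runif(n) < config$static_head_move_rate
    mov <- draw_movements(tt, moved, static_viol, pp, mp, act_sph$azimuth)
    for (k in seq_len(n)) {
      if (!is.null(mov$details[[k]]))
        mov_list[[paste0(pp$participant, "_", tt$trial[k])]] <- mov$details[[k]]
    }

    ## --- response model -------------------------------------------------
    eff <- effective_params(tt, pp, rp, mp, moved)
    ## near targets subtend larger angles for the same Cartesian noise
    dsc <- if (isTRUE(rp$angular_depth_scaling)) {
      (1 / tt$position_depth_cm) / mean(1 / unique(grid$depth_cm))
    } else rep(1, n)
    ## azimuth: eccentric bias + participant offsets + trial noise
    delta_az <- ifelse(tt$sector == "front", pp$delta_az_front, pp$delta_az_back)
    gamma_az <- gamma_lookup(pp, "az", tt$condition, tt$sector)
    az_err <- dsc * (sign(tt$position_az) * (bs * eff$az_bias + delta_az + gamma_az) +
                       stats::rnorm(n, 0, 1) * eff$az_sd * ns)
    delta_el <- ifelse(tt$sector == "front", pp$delta_el_front, pp$delta_el_back)
    gamma_el <- gamma_lookup(pp, "el", tt$condition, tt$sector)
    el_err <- dsc * (bs * eff$el_bias + delta_el + gamma_el +
                       stats::rnorm(n, 0, 1) * eff$el_sd * ns)
    depth_bias <- rp$depth_bias_cm[tt$distance]
    depth_sd <- rp$depth_sd_cm[tt$sector]
    depth_err <- bs * depth_bias + pp$delta_depth +
      stats::rnorm(n, 0, 1) * depth_sd * ns

    resp_az <- wrap_angle(act_sph$azimuth + az_err)
    resp_el <- pmin(90, pmax(-90, act_sph$elevation + el_err))
    resp_depth <- pmax(2, act_sph$depth_cm + depth_err)
    rxyz <- spherical_to_cartesian(resp_az, resp_el, resp_depth)
    if (!is.matrix(rxyz)) rxyz <- matrix(rxyz, nrow = 1)

    ## --- compliance + hand onset ----------------------------------------
    anticipatory <- stats::runif(n) < config$anticipatory_rate[tt$condition]
    hand_onset <- ifelse(anticipatory,
                         stats::runif(n, 1.5, 2.9),
                         pmax(3.05, stats::rnorm(n, pp$rt_mean,
                                                 config$hand_rt_within_sd_s * ns)))
    reason <- ifelse(static_viol, "head_move_in_static",
                     ifelse(anticipatory, "anticipatory_hand", "none"))
    ## anticipatory hand takes precedence only when the head also moved;
    ## keep labels mutually exclusive the way the offline check resolves them
    reason[static_viol & anticipatory] <- "head_move_in_static"

    ## --- reference pose & world coordinates ------------------------------
    ref <- draw_reference_poses(n, config)
    pre_w <- head_to_world_rows(ph, ref, config$head_pivot_m)
    act_w <- head_to_world_rows(ah, ref, config$head_pivot_m)

    trial_list[[i]] <- data.frame(
      participant = pp$participant, trial = tt$trial, block = tt$block,
      condition = tt$condition,
      position_az = tt$position_az, position_el = 0,
      position_depth_cm = tt$position_depth_cm,
      sector = tt$sector, distance = tt$distance,
      ph_x = ph[, 1], ph_y = ph[, 2], ph_z = ph[, 3],
      ah_x = ah[, 1], ah_y = ah[, 2], ah_z = ah[, 3],
      pre_x = pre_w[, 1], pre_y = pre_w[, 2], pre_z = pre_w[, 3],
      act_x = act_w[, 1], act_y = act_w[, 2], act_z = act_w[, 3],
      ref_x = ref$x, ref_y = ref$y, ref_z = ref$z,
      ref_qw = ref$qw, ref_qx = ref$qx, ref_qy = ref$qy, ref_qz = ref$qz,
      rx = rxyz[, 1], ry = rxyz[, 2], rz = rxyz[, 3],
      n_head_movements = mov$n_in_window,
      first_onset_s = mov$first_onset,
      first_end_azimuth = mov$first_end_az,
      hand_onset_s = hand_onset,
      stringsAsFactors = FALSE)

    gt_list[[i]] <- data.frame(
      participant = pp$participant, trial = tt$trial,
      condition = tt$condition, sector = tt$sector, distance = tt$distance,
      az_bias_eff = bs * eff$az_bias, az_sd_eff = eff$az_sd * ns,
      el_bias_eff = bs * eff$el_bias, el_sd_eff = eff$el_sd * ns,
      depth_bias_eff = bs * depth_bias, depth_sd_eff = depth_sd * ns,
      moved = moved, n_movements = mov$n_total,
      n_in_window = mov$n_in_window, first_onset_s = mov$first_onset,
      first_end_azimuth = mov$first_end_az,
      anticipatory = anticipatory, static_head_violation = static_viol,
      hand_onset_s = hand_onset, compliance_reason = reason,
      stringsAsFactors = FALSE)

    if (config$track_mode == "full") {
      for (k in seq_len(n)) {
        key <- paste0(pp$participant, "_", tt$trial[k])
        track_list[[key]] <- build_trial_tracks(
          trial_list[[i]][k, ], mov_list[[key]], config)
      }
    }
  }

  structure(list(trials = do.call(rbind, trial_list),
                 ground_truth = do.call(rbind, gt_list),
                 participants = participants,
                 movements = mov_list,
                 tracks = track_list,
                 config = config),
            class = "loc3d_cohort")
}

#' @export
print.loc3d_cohort <- function(x, ...) {
  cat(sprintf("<synthetic 3D sound-localization cohort: %d participants, %d trials%s>\n",
              nrow(x$participants), nrow(x$trials),
              if (is.null(x$tracks)) "" else ", full tracks"))
  invisible(x)
}

## ---- internal draws ------------------------------------------------------

draw_participants <- function(config) {
  n <- config$n_participants
  mp <- config$movement_params
  rp <- config$response_params
  ns <- config$noise_scale
  m <- mp$p_move_mean
  v <- (mp$p_move_sd * if (ns > 0) 1 else 0)^2
  if (v > 0) {
    ab <- m * (1 - m) / v - 1
    p_move <- stats::rbeta(n, m * ab, (1 - m) * ab)
  } else p_move <- rep(m, n)
  g <- pmax(0, pmin(1.8, p_move / mp$p_move_mean +
                      stats::rnorm(n, 0, mp$benefit_coupling_sd * ns)))
  out <- data.frame(
    participant = sprintf("P%02d", seq_len(n)),
    block_seq_active_first = seq_len(n) %% 2 == 1,
    p_move = p_move, g = g,
    onset_mean_ms = stats::rnorm(n, mp$onset_mean_ms, mp$onset_between_sd_ms * ns),
    rt_mean = pmax(3.1, stats::rnorm(n, config$hand_rt_mean_s,
                                     config$hand_rt_between_sd_s * ns)),
    delta_az_front = stats::rnorm(n, 0, rp$tau_bias_deg * ns),
    delta_az_back = stats::rnorm(n, 0, rp$tau_bias_deg * ns),
    delta_el_front = stats::rnorm(n, 0, rp$tau_bias_deg * ns),
    delta_el_back = stats::rnorm(n, 0, rp$tau_bias_deg * ns),
    delta_depth = stats::rnorm(n, 0, rp$tau_depth_cm * ns),
    stringsAsFactors = FALSE)
  for (dim in c("az", "el"))
    for (cond in c("static", "active"))
      for (sec in c("front", "back"))
        out[[paste("gamma", dim, cond, sec, sep = "_")]] <-
          stats::rnorm(n, 0, rp$tau_cell_deg * ns)
  out
}

gamma_lookup <- function(pp, dim, condition, sector)
  vapply(seq_along(condition), function(k)
    pp[[paste("gamma", dim, condition[k], sector[k], sep = "_")]], numeric(1))

## block design: ABBA counterbalance, 48 randomized trials per block
draw_trial_design <- function(config, pp, grid) {
  seq_conds <- if (pp$block_seq_active_first)
    c("active", "static", "static", "active")
  else c("static", "active", "active", "static")
  first_of_cond <- !duplicated(seq_conds)
  blocks <- lapply(1:4, function(b) {
    ## each condition's trials_per_cell reps split across its two blocks
    reps <- if (first_of_cond[b]) ceiling(config$trials_per_cell / 2)
    else floor(config$trials_per_cell / 2)
    idx <- sample(rep(seq_len(nrow(grid)), reps))
    data.frame(block = b, condition = seq_conds[b],
               position_az = grid$azimuth[idx],
               position_depth_cm = grid$depth_cm[idx],
               sector = grid$sector[idx], distance = grid$distance[idx],
               stringsAsFactors = FALSE)
  })
  tt <- do.call(rbind, blocks)
  tt$trial <- seq_len(nrow(tt))
  tt
}

## anisotropic direction x Beta radius, never outside the tolerance sphere
draw_placement_noise <- function(n, config) {
  sd3 <- config$placement_direction_sd
  v <- cbind(stats::rnorm(n, 0, sd3[1]), stats::rnorm(n, 0, sd3[2]),
             stats::rnorm(n, 0, sd3[3]))
  nv <- sqrt(rowSums(v^2))
  nv[nv == 0] <- 1
  u <- v / nv
  r <- config$placement_tolerance_cm *
    stats::rbeta(n, config$placement_radius_beta[1], config$placement_radius_beta[2])
  u * r
}

draw_movements <- function(tt, moved, static_viol, pp, mp, actual_az) {
  n <- nrow(tt)
  details <- vector("list", n)
  n_total <- integer(n)
  n_in_window <- integer(n)
  first_onset <- rep(NA_real_, n)
  first_end_az <- rep(NA_real_, n)
  for (k in seq_len(n)) {
    if (moved[k]) {
      tgt <- actual_az[k]
      if (abs(tgt) < 90) {
        end_az <- tgt * stats::rnorm(1, mp$front_gain_mean, mp$front_gain_sd) +
          stats::rnorm(1, 0, mp$front_dir_sd_deg)
      } else if (stats::runif(1) < mp$back_full_turn_prob) {
        end_az <- sign(tgt) * stats::rnorm(1, mp$back_full_mean_deg, mp$back_full_sd_deg)
      } else {
        end_az <- sign(tgt) * stats::rnorm(1, mp$back_quad_mean_deg, mp$back_quad_sd_deg)
      }
      ## reorientations below ~15 deg would not clear the 80 mm/s detector at
      ## the head's pivot radius; the model never emits them
      if (abs(end_az) < 15)
        end_az <- 15 * if (end_az == 0) sign(tgt) else sign(end_az)
      onset1 <- rnorm_trunc(1, pp$onset_mean_ms, mp$onset_within_sd_ms,
                            150, 2800) / 1000
      deltas <- end_az
      onsets <- onset1
      extra <- stats::rpois(1, mp$extra_movement_rate)
      if (extra > 0) {
        cur_off <- onset1 + yaw_duration(end_az)
        sgn <- -sign(end_az)
        for (e in seq_len(extra)) {
          o <- cur_off + stats::runif(1, 0.15, 0.45)
          d <- sgn * max(15, stats::rnorm(1, 22, 5))
          deltas <- c(deltas, d)
          onsets <- c(onsets, o)
          cur_off <- o + yaw_duration(d)
          sgn <- -sgn
        }
      }
      details[[k]] <- data.frame(onset = onsets, delta = deltas,
                                 duration = yaw_duration(deltas))
    } else if (static_viol[k]) {
      d <- sign(stats::runif(1) - 0.5) * stats::rnorm(1, 25, 5)
      details[[k]] <- data.frame(onset = stats::runif(1, 0.5, 2.5), delta = d,
                                 duration = yaw_duration(d))
    }
    if (!is.null(details[[k]])) {
      n_total[k] <- nrow(details[[k]])
      inwin <- details[[k]]$onset >= 0 & details[[k]]$onset <= 3
      n_in_window[k] <- sum(inwin)
      if (any(inwin)) {
        first_onset[k] <- details[[k]]$onset[which(inwin)[1]]
        first_end_az[k] <- cumsum(details[[k]]$delta)[which(inwin)[1]]
      }
    }
  }
  list(details = details, n_total = n_total, n_in_window = n_in_window,
       first_onset = first_onset, first_end_az = first_end_az)
}

## condition x sector effective bias/SD; active cells interpolate from the
## static values toward the nominal active values by the participant's
## improvement factor g (variance-scale interpolation for the SDs)
effective_params <- function(tt, pp, rp, mp, moved) {
  look <- function(dim, col) {
    a <- rp$angular
    vapply(seq_len(nrow(tt)), function(k)
      a[[col]][a$dimension == dim & a$sector == tt$sector[k]], numeric(1))
  }
  interp_bias <- function(bs, ba, active, g) ifelse(active, bs + g * (ba - bs), bs)
  interp_sd <- function(ss, sa, active, g)
    ifelse(active,
           sqrt(pmax((0.4 * sa)^2, ss^2 + g * (sa^2 - ss^2))),
           ss)
  active <- tt$condition == "active"
  list(
    az_bias = interp_bias(look("azimuth", "bias_static"),
                          look("azimuth", "bias_active"), active, pp$g),
    az_sd = interp_sd(look("azimuth", "sd_static"),
                      look("azimuth", "sd_active"), active, pp$g),
    el_bias = interp_bias(look("elevation", "bias_static"),
                          look("elevation", "bias_active"), active, pp$g),
    el_sd = interp_sd(look("elevation", "sd_static"),
                      look("elevation", "sd_active"), active, pp$g))
}

## per-trial delivery-onset reference pose: head near the room center with
## between-trial postural variability and a small aligned yaw jitter
draw_reference_poses <- function(n, config) {
  ns <- config$noise_scale
  pos <- cbind(stats::rnorm(n, 0, config$head_base_sd_m * ns),
               stats::rnorm(n, 0, config$head_base_sd_m * ns),
               1.2 + stats::rnorm(n, 0, config$head_base_sd_m * ns))
  yaw <- rnorm_trunc(n, 0, 1.5 * ns, -4, 4)
  q <- t(vapply(yaw, quat_yaw, numeric(4)))
  data.frame(x = pos[, 1], y = pos[, 2], z = pos[, 3],
             qw = q[, 1], qx = q[, 2], qy = q[, 3], qz = q[, 4],
             yaw = yaw)
}

## head-frame points -> world, given marker reference poses (row-wise)
head_to_world_rows <- function(ph, ref, pivot) {
  out <- matrix(NA_real_, nrow(ph), 3)
  for (k in seq_len(nrow(ph))) {
    rp <- pose(0, c(ref$x[k], ref$y[k], ref$z[k]),
               c(ref$qw[k], ref$qx[k], ref$qy[k], ref$qz[k]))
    out[k, ] <- from_head_frame(ph[k, ], rp, c(0, -pivot, 0))
  }
  out
}
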