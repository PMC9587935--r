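#' Run the full localization-analysis pipeline
#'
#' Ties the stages together: delivery gating, head-centered re-referencing,
#' kinematic movement extraction, compliance-based trial rejection,
#' localization-error statistics, and the statistical battery (ANOVAs,
#' Holm-adjusted contrasts, Kendall correlations). Works on cohorts with
#' full tracks (the kinematic stage recomputes everything from the raw
#' world-frame time series) or on trial-level cohorts that already carry
#' kinematic annotations.
#'
#' Aggregation always proceeds trial -> participant mean -> group mean with
#' standard errors over participants; trials are never pooled across
#' participants. Outputs report angles in degrees, distances in cm and
#' times in ms.
#'
#' @param cohort A `loc3d_cohort` ([generate_experiment()] or
#'   [load_trials()]).
#' @param gating A [gating_criteria()] object (used with full tracks).
#' @param kin A [kin_settings()] object.
#' @param dispersion Dispersion rule for the 3D random error, see
#'   [error_3d()].
#' @param head_center_offset Body-frame offset from the tracked head marker
#'   to the head center, meters; defaults to the cohort's configuration.
#' @return An object of class `"loc3d_run"` with components `trials` (with
#'   rejection flags), `records` (accepted responses with per-dimension
#'   errors), `placement`, `participant_errors`, `error3d`,
#'   `error3d_sector`, `head_movements`, `anovas`, `contrasts`,
#'   `correlations` and `manifest`; `print()` and `summary()` methods give
#'   condensed and full reports.
#' @export
run_pipeline <- function(cohort, gating = gating_criteria(),
                         kin = kin_settings(),
                         dispersion = c("rms3d", "axis_mean"),
                         head_center_offset = NULL) {
  stopifnot(inherits(cohort, "loc3d_cohort"))
  dispersion <- match.arg(dispersion)
  if (is.null(head_center_offset))
    head_center_offset <- if (!is.null(cohort$config))
      c(0, -cohort$config$head_pivot_m, 0) else c(0, 0, 0)

  trials <- cohort$trials
  if (!is.null(cohort$tracks)) {
    trials <- kinematic_stage(trials, cohort$tracks, gating, kin,
                              head_center_offset)
  } else {
    need <- c("n_head_movements", "first_onset_s", "hand_onset_s", "rx", "ry", "rz")
    if (!all(need %in% names(trials)))
      stop("pipeline stage 'kinematics': cohort has no tracks and the trial ",
           "table lacks kinematic annotations (",
           paste(setdiff(need, names(trials)), collapse = ", "), ")",
           call. = FALSE)
  }

  ## ---- compliance-based rejection --------------------------------------
  w2 <- kin$sound_window_s[2]
  head_in_sound <- !is.na(trials$first_onset_s) &
    trials$first_onset_s > kin$sound_window_s[1] & trials$first_onset_s < w2 &
    trials$n_head_movements > 0
  reason <- ifelse(trials$condition == "static" & head_in_sound,
                   "head_move_in_static",
                   ifelse(trials$hand_onset_s < w2, "anticipatory_hand", "none"))
  trials$rejected <- reason != "none"
  trials$reject_reason <- reason

  manifest <- build_manifest(cohort, trials, kin, gating, dispersion)

  accepted <- trials[!trials$rejected, , drop = FALSE]
  records <- data.frame(
    participant = accepted$participant, trial = accepted$trial,
    condition = accepted$condition, sector = accepted$sector,
    distance = accepted$distance,
    position_az = accepted$position_az,
    position_depth_cm = accepted$position_depth_cm,
    rx = accepted$rx, ry = accepted$ry, rz = accepted$rz,
    tx = accepted$ah_x, ty = accepted$ah_y, tz = accepted$ah_z,
    stringsAsFactors = FALSE)
  records <- dimension_errors(records)

  placement <- placement_accuracy(trials)
  pe <- suppressWarnings(participant_errors(records))
  e3 <- error_3d(records, by = c("participant", "condition"),
                 dispersion = dispersion)
  e3s <- error_3d(records, by = c("participant", "condition", "sector"),
                  dispersion = dispersion)

  hm <- head_movement_stage(trials, kin)
  stats_out <- stats_stage(pe, e3, e3s, hm)

  structure(list(trials = trials, records = records, placement = placement,
                 participant_errors = pe, error3d = e3, error3d_sector = e3s,
                 head_movements = hm, anovas = stats_out$anovas,
                 contrasts = stats_out$contrasts,
                 correlations = stats_out$correlations,
                 manifest = manifest),
            class = "loc3d_run")
}

## per-trial kinematic analysis from raw tracks
kinematic_stage <- function(trials, tracks, gating, kin, head_center_offset) {
  out <- trials
  cols <- c("n_head_movements", "first_onset_s", "first_end_azimuth",
            "hand_onset_s", "rx", "ry", "rz",
            "ah_x", "ah_y", "ah_z", "ph_x", "ph_y", "ph_z")
  for (cc in cols) out[[cc]] <- NA_real_
  for (i in seq_len(nrow(trials))) {
    key <- paste0(trials$participant[i], "_", trials$trial[i])
    tk <- tracks[[key]]
    if (is.null(tk))
      stop("pipeline stage 'kinematics': missing tracks for trial ", key,
           call. = FALSE)
    res <- analyze_trial_tracks(trials[i, ], tk, gating, kin, head_center_offset)
    for (cc in names(res)) out[[cc]][i] <- res[[cc]]
  }
  out
}

analyze_trial_tracks <- function(tr, tk, gating, kin, head_center_offset) {
  target_world <- c(tr$pre_x, tr$pre_y, tr$pre_z)
  t0 <- find_delivery_onset(tk$head, tk$eye, tk$speaker, target_world, gating)
  head <- tk$head; hand <- tk$hand; speaker <- tk$speaker
  head$t <- head$t - t0; hand$t <- hand$t - t0; speaker$t <- speaker$t - t0

  i0 <- which.min(abs(head$t))
  ref <- pose(0, c(head$x[i0], head$y[i0], head$z[i0]),
              c(head$qw[i0], head$qx[i0], head$qy[i0], head$qz[i0]))
  fs <- 1 / stats::median(diff(head$t))

  filt <- function(d) suppressWarnings(
    lowpass_filter(as.matrix(d[, c("x", "y", "z")]), fs, kin$cutoff_hz))
  hpos <- filt(head); hdpos <- filt(hand)
  hseg <- segment_movements(speed_series(hpos, fs, head$t),
                            kin$threshold_mm_s, kin$min_duration_ms)
  dseg <- segment_movements(speed_series(hdpos, fs, hand$t),
                            kin$threshold_mm_s, kin$min_duration_ms)

  ## head facing azimuth relative to the delivery-onset pose
  Rref <- quat_to_rotmat(ref$orientation)
  fx <- 2 * (head$qx * head$qy - head$qw * head$qz)
  fy <- 1 - 2 * (head$qx^2 + head$qz^2)
  fz <- 2 * (head$qy * head$qz + head$qw * head$qx)
  f_rel <- cbind(fx, fy, fz) %*% Rref
  head_az <- data.frame(t = head$t,
                        azimuth = atan2(f_rel[, 1], f_rel[, 2]) * 180 / pi)

  metrics <- head_movement_metrics(hseg, head_az, kin$sound_window_s)

  ## response = hand position at the offset of the last hand movement
  if (nrow(dseg) == 0L)
    stop("pipeline stage 'kinematics': no hand movement found in trial ",
         tr$participant, "_", tr$trial, call. = FALSE)
  last <- dseg[nrow(dseg), ]
  ir <- which.min(abs(hand$t - last$offset))
  resp_head <- to_head_frame(hdpos[ir, ], ref, head_center_offset)

  isp <- max(which(speaker$t <= 0))
  act_head <- to_head_frame(c(speaker$x[isp], speaker$y[isp], speaker$z[isp]),
                            ref, head_center_offset)
  pred_head <- to_head_frame(target_world, ref, head_center_offset)

  list(n_head_movements = metrics$n_movements,
       first_onset_s = metrics$first_onset,
       first_end_azimuth = metrics$first_end_azimuth,
       hand_onset_s = dseg$onset[1],
       rx = resp_head[1], ry = resp_head[2], rz = resp_head[3],
       ah_x = act_head[1], ah_y = act_head[2], ah_z = act_head[3],
       ph_x = pred_head[1], ph_y = pred_head[2], ph_z = pred_head[3])
}

## head-movement descriptives on active accepted trials, with the IQR
## outlier rule on the per-participant percentage of trials with movements
head_movement_stage <- function(trials, kin) {
  act <- trials[trials$condition == "active" & !trials$rejected, , drop = FALSE]
  if (nrow(act) == 0L) return(NULL)
  per <- aggregate_by(act, "participant", function(idx) {
    n <- act$n_head_movements[idx]
    on <- act$first_onset_s[idx]
    moved <- n > 0
    c(pct_moved = 100 * mean(moved),
      mean_n_movements = if (any(moved)) mean(n[moved]) else NA_real_,
      mean_n_all_trials = mean(n),
      mean_onset_ms = if (any(moved)) 1000 * mean(on[moved], na.rm = TRUE) else NA_real_,
      n_trials = length(idx))
  })
  outlier <- if (nrow(per) >= 4L) detect_movement_outliers(per$pct_moved)
  else rep(FALSE, nrow(per))
  per$outlier <- as.logical(outlier)
  keep <- per$participant[!per$outlier]
  sub <- act[act$participant %in% keep & act$n_head_movements > 0, , drop = FALSE]
  dirs <- if (nrow(sub)) {
    d <- aggregate_by(sub, "position_az", function(idx)
      c(mean_first_end_azimuth = mean(sub$first_end_azimuth[idx], na.rm = TRUE),
        n = length(idx)))
    d$position_az <- as.numeric(d$position_az)
    d
  } else NULL
  list(per_participant = per, outliers = per$participant[per$outlier],
       directions = dirs,
       summary = c(
         pct_moved = mean(per$pct_moved[!per$outlier]),
         mean_n_movements = mean(per$mean_n_movements[!per$outlier], na.rm = TRUE),
         mean_onset_ms = mean(per$mean_onset_ms[!per$outlier], na.rm = TRUE)))
}

stats_stage <- function(pe, e3, e3s, hm) {
  ang <- pe$angular
  n_part <- length(unique(ang$participant))
  if (n_part < 3L || length(unique(ang$condition)) < 2L)
    return(list(anovas = NULL, contrasts = NULL, correlations = NULL))

  ## a cohort can lose a whole design cell to rejections; report what can
  ## be computed and drop the rest rather than aborting the run
  safe <- function(expr) tryCatch(expr, error = function(e) NULL)
  anovas <- list(
    azimuth_abs = safe(rm_anova(ang, "az_abs", "participant", c("condition", "sector"))),
    azimuth_var = safe(rm_anova(ang, "az_var", "participant", c("condition", "sector"))),
    elevation_abs = safe(rm_anova(ang, "el_abs", "participant", c("condition", "sector"))),
    elevation_var = safe(rm_anova(ang, "el_var", "participant", c("condition", "sector"))),
    depth_abs = safe(rm_anova(pe$depth, "depth_abs_cm", "participant",
                              c("condition", "sector", "distance"))),
    depth_var = safe(rm_anova(pe$depth, "depth_var_cm", "participant",
                              c("condition", "sector", "distance"))),
    depth_response = safe(rm_anova(
      stats::aggregate(response_depth_cm ~ participant + distance, pe$depth, mean),
      "response_depth_cm", "participant", "distance")),
    error3d = safe(rm_anova(e3s, "error_3d", "participant", c("condition", "sector"))))
  anovas <- Filter(Negate(is.null), anovas)

  contrasts <- Filter(Negate(is.null), list(
    azimuth_abs = safe(condition_contrast(ang, "az_abs", "participant",
                                          "condition", by = "sector")),
    elevation_abs = safe(condition_contrast(ang, "el_abs", "participant",
                                            "condition", by = "sector")),
    error3d = safe(condition_contrast(e3s, "error_3d", "participant",
                                      "condition", by = "sector"))))

  correlations <- NULL
  if (!is.null(hm)) {
    wide <- merge(e3[e3$condition == "static", c("participant", "error_3d")],
                  e3[e3$condition == "active", c("participant", "error_3d")],
                  by = "participant", suffixes = c("_static", "_active"))
    wide$improvement <- (wide$error_3d_static - wide$error_3d_active) /
      wide$error_3d_static
    keep <- hm$per_participant[!hm$per_participant$outlier, ]
    wide <- merge(wide, keep[, c("participant", "pct_moved", "mean_n_all_trials")],
                  by = "participant")
    correlations <- tryCatch(list(
      improvement_vs_pct_moved =
        kendall_correlation(wide$pct_moved, wide$improvement),
      improvement_vs_mean_n =
        kendall_correlation(wide$mean_n_all_trials, wide$improvement)),
      error = function(e) NULL)
  }
  list(anovas = anovas, contrasts = contrasts, correlations = correlations)
}

build_manifest <- function(cohort, trials, kin, gating, dispersion) {
  rej_pct <- vapply(split(trials$rejected, trials$condition),
                    function(r) 100 * mean(r), numeric(1))
  list(package_version = as.character(utils::packageVersion("soundloc3d")),
       n_participants = length(unique(trials$participant)),
       n_trials = nrow(trials),
       n_accepted = sum(!trials$rejected),
       n_rejected = sum(trials$rejected),
       rejected_by_reason = table(trials$reject_reason[trials$rejected]),
       rejected_pct_by_condition = rej_pct,
       seed = if (!is.null(cohort$config)) cohort$config$seed else NA,
       settings = list(kin = unclass(kin), gating = unclass(gating),
                       dispersion = dispersion))
}

#' @export
print.loc3d_run <- function(x, ...) {
  m <- x$manifest
  cat("3D sound-localization pipeline run\n")
  cat(sprintf("  %d participants, %d trials (%d accepted, %d rejected)\n",
              m$n_participants, m$n_trials, m$n_accepted, m$n_rejected))
  if (length(m$rejected_pct_by_condition))
    cat(sprintf("  rejection rate: %s\n",
                paste(sprintf("%s %.1f%%", names(m$rejected_pct_by_condition),
                              m$rejected_pct_by_condition), collapse = ", ")))
  cat(sprintf("  speaker placement: |x| %.2f, |y| %.2f, |z| %.2f cm; 3D %.2f cm\n",
              x$placement$per_axis_cm[1], x$placement$per_axis_cm[2],
              x$placement$per_axis_cm[3], x$placement$norm_3d_cm))
  e3 <- stats::aggregate(error_3d ~ condition, x$error3d, mean)
  cat(sprintf("  3D error: %s\n",
              paste(sprintf("%s %.1f cm", e3$condition, e3$error_3d),
                    collapse = ", ")))
  if (!is.null(x$head_movements))
    cat(sprintf("  head movements (active): %.1f%% of trials, %.2f per trial, onset %.0f ms\n",
                x$head_movements$summary["pct_moved"],
                x$head_movements$summary["mean_n_movements"],
                x$head_movements$summary["mean_onset_ms"]))
  invisible(x)
}

#' @export
summary.loc3d_run <- function(object, ...) {
  print(object)
  if (!is.null(object$anovas)) {
    for (nm in names(object$anovas)) {
      cat("\n==", nm, "==\n")
      print(object$anovas[[nm]])
    }
    for (nm in names(object$contrasts)) {
      cat("\n== contrast:", nm, "==\n")
      print(object$contrasts[[nm]])
    }
    if (!is.null(object$correlations)) {
      cat("\n== correlations ==\n")
      for (nm in names(object$correlations)) {
        cat(sprintf("  %s: ", nm)); print(object$correlations[[nm]])
      }
    }
  }
  invisible(object)
}

#' Write pipeline outputs to disk
#'
#' Emits tidy CSV tables (accepted records, per-participant error tables,
#' 3D-error summaries, head-movement table), a machine-readable stats report
#' (one row per ANOVA term and contrast), and a plain-text manifest with
#' row-count bookkeeping and MD5 checksums of every written table.
#'
#' @param run A `loc3d_run`.
#' @param dir Output directory.
#' @return `dir`, invisibly.
#' @export
write_results <- function(run, dir) {
  stopifnot(inherits(run, "loc3d_run"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  wr <- function(d, f) utils::write.csv(d, file.path(dir, f), row.names = FALSE)
  wr(run$records, "records.csv")
  wr(run$participant_errors$angular, "errors_angular.csv")
  wr(run$participant_errors$depth, "errors_depth.csv")
  wr(run$error3d, "error3d.csv")
  wr(run$error3d_sector, "error3d_sector.csv")
  if (!is.null(run$head_movements))
    wr(run$head_movements$per_participant, "head_movements.csv")
  if (!is.null(run$anovas)) {
    rep_rows <- do.call(rbind, lapply(names(run$anovas), function(nm) {
      a <- run$anovas[[nm]]
      data.frame(analysis = nm, a, stringsAsFactors = FALSE)
    }))
    wr(rep_rows, "stats_anova.csv")
    con_rows <- do.call(rbind, lapply(names(run$contrasts), function(nm) {
      d <- run$contrasts[[nm]]
      data.frame(analysis = nm, as.data.frame(d), stringsAsFactors = FALSE)
    }))
    wr(con_rows, "stats_contrasts.csv")
  }
  m <- run$manifest
  files <- list.files(dir, pattern = "\\.csv$", full.names = TRUE)
  sums <- tools::md5sum(files)
  lines <- c(
    sprintf("package_version: %s", m$package_version),
    sprintf("seed: %s", m$seed),
    sprintf("n_participants: %d", m$n_participants),
    sprintf("n_trials: %d", m$n_trials),
    sprintf("n_accepted: %d", m$n_accepted),
    sprintf("n_rejected: %d", m$n_rejected),
    sprintf("checksum %s: %s", basename(names(sums)), unname(sums)))
  writeLines(lines, file.path(dir, "manifest.txt"))
  invisible(dir)
}
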