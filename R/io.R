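## File interfaces: trial tables and long-format track files.
##
## Track schema (one CSV per participant): columns participant, trial, body
## in {head, eye, hand, speaker}, t, x, y, z, qw, qx, qy, qz; quaternion
## columns are empty (NA) for point-only bodies. Units are meters and
## seconds, stated in a leading comment line.

track_header <- "# soundloc3d track file: units meters/seconds; world frame; quaternion (w,x,y,z) for rigid bodies, empty for point bodies"

#' Write a synthetic cohort to disk
#'
#' Emits `trials.csv`, `ground_truth.csv`, `participants.csv` and, when full
#' tracks are present, one long-format `tracks_<participant>.csv` per
#' participant in the documented schema.
#'
#' @param cohort A `loc3d_cohort` from [generate_experiment()].
#' @param dir Output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cohort <- function(cohort, dir) {
  stopifnot(inherits(cohort, "loc3d_cohort"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  utils::write.csv(cohort$trials, file.path(dir, "trials.csv"), row.names = FALSE)
  utils::write.csv(cohort$ground_truth, file.path(dir, "ground_truth.csv"),
                   row.names = FALSE)
  utils::write.csv(cohort$participants, file.path(dir, "participants.csv"),
                   row.names = FALSE)
  if (!is.null(cohort$tracks)) {
    for (p in unique(cohort$trials$participant)) {
      rows <- cohort$trials[cohort$trials$participant == p, ]
      long <- do.call(rbind, lapply(rows$trial, function(tr) {
        tk <- cohort$tracks[[paste0(p, "_", tr)]]
        do.call(rbind, lapply(names(tk), function(body) {
          d <- tk[[body]]
          data.frame(participant = p, trial = tr, body = body, t = d$t,
                     x = d$x, y = d$y, z = d$z,
                     qw = if ("qw" %in% names(d)) d$qw else NA_real_,
                     qx = if ("qx" %in% names(d)) d$qx else NA_real_,
                     qy = if ("qy" %in% names(d)) d$qy else NA_real_,
                     qz = if ("qz" %in% names(d)) d$qz else NA_real_)
        }))
      }))
      path <- file.path(dir, sprintf("tracks_%s.csv", p))
      writeLines(track_header, path)
      suppressWarnings(utils::write.table(long, path, sep = ",", quote = FALSE,
                                          row.names = FALSE, col.names = TRUE,
                                          append = TRUE))
    }
  }
  invisible(dir)
}

#' Load a trial set from disk with schema validation
#'
#' Reads the trial table and any long-format track files written by
#' [write_cohort()] (or prepared externally in the same schema), validates
#' them, and reassembles an in-memory cohort. Validation failures are
#' reported with the offending file, row and column.
#'
#' @param dir Directory holding `trials.csv` and optional
#'   `tracks_<participant>.csv` files.
#' @return A `loc3d_cohort` (without generator config/ground truth unless
#'   those files are present).
#' @export
load_trials <- function(dir) {
  tf <- file.path(dir, "trials.csv")
  if (!file.exists(tf)) stop("trials.csv not found in ", dir, call. = FALSE)
  trials <- utils::read.csv(tf, stringsAsFactors = FALSE)
  need <- c("participant", "trial", "condition", "position_az",
            "position_depth_cm", "sector", "distance",
            "ph_x", "ph_y", "ph_z", "ah_x", "ah_y", "ah_z")
  missing_cols <- setdiff(need, names(trials))
  if (length(missing_cols))
    stop(sprintf("%s: missing required column(s): %s", tf,
                 paste(missing_cols, collapse = ", ")), call. = FALSE)

  gt <- NULL
  gtf <- file.path(dir, "ground_truth.csv")
  if (file.exists(gtf)) gt <- utils::read.csv(gtf, stringsAsFactors = FALSE)

  track_files <- list.files(dir, pattern = "^tracks_.*\\.csv$", full.names = TRUE)
  tracks <- NULL
  if (length(track_files)) {
    tracks <- list()
    for (f in track_files) {
      long <- utils::read.csv(f, comment.char = "#", stringsAsFactors = FALSE)
      head_rows <- which(long$body == "head")
      qn <- sqrt(long$qw[head_rows]^2 + long$qx[head_rows]^2 +
                   long$qy[head_rows]^2 + long$qz[head_rows]^2)
      bad <- which(abs(qn - 1) > 1e-6 | !is.finite(qn))
      if (length(bad))
        stop(sprintf("%s: non-unit head quaternion at row %d (|q| = %.6g)",
                     f, head_rows[bad[1]], qn[bad[1]]), call. = FALSE)
      if (any(!is.finite(long$t)))
        stop(sprintf("%s: non-finite time stamp at row %d", f,
                     which(!is.finite(long$t))[1]), call. = FALSE)
      for (tr in unique(long$trial)) {
        sub <- long[long$trial == tr, ]
        p <- sub$participant[1]
        tk <- list()
        for (body in unique(sub$body)) {
          d <- sub[sub$body == body, c("t", "x", "y", "z", "qw", "qx", "qy", "qz")]
          if (all(is.na(d$qw))) d <- d[, c("t", "x", "y", "z")]
          rownames(d) <- NULL
          tk[[body]] <- d
        }
        tracks[[paste0(p, "_", tr)]] <- tk
      }
    }
    missing_tracks <- setdiff(paste0(trials$participant, "_", trials$trial),
                              names(tracks))
    if (length(missing_tracks))
      stop("trial table references missing tracks for: ",
           paste(utils::head(missing_tracks, 5L), collapse = ", "),
           call. = FALSE)
  }

  structure(list(trials = trials, ground_truth = gt, participants = NULL,
                 movements = NULL, tracks = tracks, config = NULL),
            class = "loc3d_cohort")
}
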