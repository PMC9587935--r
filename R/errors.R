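#' Wrap angles into (-180, 180]
#'
#' @param a Angles in degrees.
#' @return Wrapped angles.
#' @export
wrap_angle <- function(a) {
  w <- a %% 360
  w[w > 180] <- w[w > 180] - 360
  w
}

#' Per-dimension localization errors
#'
#' Computes signed and absolute errors per response record: azimuth error is
#' the circular difference response - target wrapped into (-180, 180];
#' elevation error is the plain angular difference (all targets sit at
#' ear-level 0 degrees); depth error is response depth minus target depth in
#' cm. Records whose response collapses onto the head center (zero depth)
#' are flagged degenerate and should be excluded from aggregates.
#'
#' @param records Data frame with head-frame response coordinates `rx`, `ry`,
#'   `rz` and target (speaker-at-delivery) coordinates `tx`, `ty`, `tz`,
#'   meters.
#' @return `records` with added columns `response_az`, `response_el`,
#'   `response_depth_cm`, `target_az`, `target_el`, `target_depth_cm`,
#'   `az_signed`, `az_abs`, `el_signed`, `el_abs`, `depth_signed_cm`,
#'   `depth_abs_cm`, `degenerate`.
#' @export
dimension_errors <- function(records) {
  need <- c("rx", "ry", "rz", "tx", "ty", "tz")
  if (!all(need %in% names(records)))
    stop("records must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  resp <- cartesian_to_spherical(as.matrix(records[, c("rx", "ry", "rz")]))
  targ <- cartesian_to_spherical(as.matrix(records[, c("tx", "ty", "tz")]))
  records$response_az <- resp$azimuth
  records$response_el <- resp$elevation
  records$response_depth_cm <- resp$depth_cm
  records$target_az <- targ$azimuth
  records$target_el <- targ$elevation
  records$target_depth_cm <- targ$depth_cm
  records$az_signed <- wrap_angle(resp$azimuth - targ$azimuth)
  records$az_abs <- abs(records$az_signed)
  records$el_signed <- resp$elevation - targ$elevation
  records$el_abs <- abs(records$el_signed)
  records$depth_signed_cm <- resp$depth_cm - targ$depth_cm
  records$depth_abs_cm <- abs(records$depth_signed_cm)
  records$degenerate <- resp$degenerate | targ$degenerate
  records
}

## split helper: positions are identified by the nominal target (azimuth x
## depth), so repeated stimulations of one position group together even
## though the actual speaker location varies inside the tolerance sphere
position_id <- function(records) {
  paste(records$position_az, records$position_depth_cm, sep = "@")
}

#' Variable (random) error
#'
#' Precision measure: the standard deviation (n - 1 denominator) of the
#' responses at each sound position, averaged with equal weight across the
#' positions of the stratum. Positions with fewer than 2 accepted trials are
#' skipped with a warning.
#'
#' @param records Output of [dimension_errors()] including grouping columns
#'   and nominal position columns `position_az`, `position_depth_cm`.
#' @param value Column holding the per-trial response value whose dispersion
#'   is wanted (e.g. `"response_az"`, `"response_el"`, `"response_depth_cm"`).
#' @param by Character vector of grouping columns (default participant x
#'   condition x sector).
#' @param circular Treat the value as an angle in degrees: dispersions are
#'   computed on deviations from the circular mean, wrapped into
#'   (-180, 180], so that responses straddling the +-180 degree seam (back
#'   space) are not inflated by the wrap.
#' @return Data frame: grouping columns, `variable_error`, `n_positions`.
#' @export
variable_error <- function(records, value,
                           by = c("participant", "condition", "sector"),
                           circular = FALSE) {
  stopifnot(value %in% names(records), all(by %in% names(records)))
  pid <- position_id(records)
  sd_fn <- if (circular) circular_sd else stats::sd
  skipped <- 0L
  agg <- aggregate_by(records, by, function(idx) {
    v <- records[[value]][idx]
    p <- pid[idx]
    sds <- tapply(v, p, function(z) if (length(z) >= 2L) sd_fn(z) else NA_real_)
    skipped <<- skipped + sum(is.na(sds))
    c(variable_error = mean(sds, na.rm = TRUE), n_positions = sum(!is.na(sds)))
  })
  if (skipped > 0L)
    warning(sprintf("%d position(s) with < 2 trials skipped in variable error",
                    skipped), call. = FALSE)
  agg
}

## dispersion of angles: SD of wrapped deviations from the circular mean
circular_sd <- function(z) {
  rad <- z * pi / 180
  center <- atan2(mean(sin(rad)), mean(cos(rad))) * 180 / pi
  stats::sd(wrap_angle(z - center))
}

## minimal grouped-apply returning a data frame (base R, stable order)
aggregate_by <- function(df, by, fn) {
  key <- interaction(df[by], drop = TRUE, lex.order = TRUE, sep = "\r")
  idx_list <- split(seq_len(nrow(df)), key)
  vals <- t(vapply(idx_list, fn, fn(idx_list[[1]])))
  keys <- do.call(rbind, strsplit(names(idx_list), "\r", fixed = TRUE))
  out <- data.frame(keys, vals, stringsAsFactors = FALSE, row.names = NULL)
  names(out) <- c(by, colnames(vals))
  for (v in colnames(vals)) out[[v]] <- as.numeric(out[[v]])
  out
}

#' Composite 3D localization error
#'
#' For each stratum (participant x condition by default) the per-trial 3D
#' constant error is `C_i = 100 ||response_i - target_i||` (cm), with the
#' target taken as the actual speaker position at delivery. `C_bar` averages
#' `C_i` over all accepted trials irrespective of sound position. The random
#' term `s_bar` averages a per-position dispersion of the 3D responses across
#' positions; two dispersion definitions are available:
#' `"rms3d"` (default) uses `sqrt(var_x + var_y + var_z)`, the RMS distance
#' from the position's mean response, and `"axis_mean"` uses the mean of the
#' three per-axis standard deviations. The composite index is
#' `error_3d = sqrt(C_bar^2 + s_bar^2)`.
#'
#' @param records Data frame with head-frame `rx`, `ry`, `rz`, `tx`, `ty`,
#'   `tz` (meters) plus nominal position columns and the grouping columns.
#' @param by Grouping columns (default `c("participant", "condition")`).
#' @param dispersion `"rms3d"` or `"axis_mean"`.
#' @return Data frame: grouping columns, `C_bar`, `s_bar`, `error_3d` (cm),
#'   `n_trials`, `n_positions`.
#' @export
error_3d <- function(records, by = c("participant", "condition"),
                     dispersion = c("rms3d", "axis_mean")) {
  dispersion <- match.arg(dispersion)
  if (nrow(records) == 0L)
    stop("no accepted trials: cannot compute the 3D error", call. = FALSE)
  pid <- position_id(records)
  R <- as.matrix(records[, c("rx", "ry", "rz")]) * 100  # cm
  Tg <- as.matrix(records[, c("tx", "ty", "tz")]) * 100
  Ci <- sqrt(rowSums((R - Tg)^2))
  aggregate_by(records, by, function(idx) {
    C_bar <- mean(Ci[idx])
    disp <- tapply(idx, pid[idx], function(ii) {
      if (length(ii) < 2L) return(NA_real_)
      v <- apply(R[ii, , drop = FALSE], 2, stats::var)
      if (dispersion == "rms3d") sqrt(sum(v)) else mean(sqrt(v))
    })
    s_bar <- mean(disp, na.rm = TRUE)
    if (!is.finite(s_bar)) s_bar <- NA_real_
    c(C_bar = C_bar, s_bar = s_bar,
      error_3d = sqrt(C_bar^2 + s_bar^2),
      n_trials = length(idx), n_positions = sum(!is.na(disp)))
  })
}

#' Speaker-placement accuracy
#'
#' Per-axis mean absolute difference and mean 3D Euclidean norm between the
#' predetermined and the actual speaker location across all stimulations,
#' in centimeters (head-frame axes: x right, y forward, z up).
#'
#' @param trials Data frame with predetermined head-frame columns `ph_x`,
#'   `ph_y`, `ph_z` and actual columns `ah_x`, `ah_y`, `ah_z` (meters).
#' @return A list with `per_axis_cm` (named x/y/z), `norm_3d_cm` and `n`.
#' @export
placement_accuracy <- function(trials) {
  need <- c("ph_x", "ph_y", "ph_z", "ah_x", "ah_y", "ah_z")
  if (!all(need %in% names(trials)))
    stop("trials must contain columns ", paste(need, collapse = ", "),
         call. = FALSE)
  d <- 100 * (as.matrix(trials[, c("ah_x", "ah_y", "ah_z")]) -
                as.matrix(trials[, c("ph_x", "ph_y", "ph_z")]))
  list(per_axis_cm = stats::setNames(colMeans(abs(d)), c("x", "y", "z")),
       norm_3d_cm = mean(sqrt(rowSums(d^2))),
       n = nrow(d))
}

#' Per-participant error summary tables
#'
#' Aggregates accepted response records into the per-participant cell values
#' entered in the statistical analyses: mean absolute and mean signed errors
#' plus variable errors for azimuth and elevation per condition x sector, and
#' for depth per condition x sector x distance (with the mean response depth,
#' the quantity used to check that the three distances are perceived as
#' distinct).
#'
#' @param records Output of [dimension_errors()] with columns `participant`,
#'   `condition`, `sector`, `distance`, `position_az`, `position_depth_cm`.
#' @return A list with data frames `angular` (azimuth/elevation cells) and
#'   `depth` (depth cells).
#' @export
participant_errors <- function(records) {
  records <- records[!records$degenerate, , drop = FALSE]
  ang <- aggregate_by(records, c("participant", "condition", "sector"),
                      function(idx) c(
                        az_abs = mean(records$az_abs[idx]),
                        az_signed = mean(records$az_signed[idx]),
                        el_abs = mean(records$el_abs[idx]),
                        el_signed = mean(records$el_signed[idx]),
                        n_trials = length(idx)))
  av <- variable_error(records, "response_az",
                       c("participant", "condition", "sector"),
                       circular = TRUE)
  ev <- variable_error(records, "response_el",
                       c("participant", "condition", "sector"))
  ang$az_var <- av$variable_error[match_rows(ang, av,
                                             c("participant", "condition", "sector"))]
  ang$el_var <- ev$variable_error[match_rows(ang, ev,
                                             c("participant", "condition", "sector"))]
  dep <- aggregate_by(records, c("participant", "condition", "sector", "distance"),
                      function(idx) c(
                        depth_abs_cm = mean(records$depth_abs_cm[idx]),
                        depth_signed_cm = mean(records$depth_signed_cm[idx]),
                        response_depth_cm = mean(records$response_depth_cm[idx]),
                        n_trials = length(idx)))
  dv <- variable_error(records, "response_depth_cm",
                       c("participant", "condition", "sector", "distance"))
  dep$depth_var_cm <- dv$variable_error[match_rows(dep, dv,
                                                   c("participant", "condition", "sector", "distance"))]
  list(angular = ang, depth = dep)
}

match_rows <- function(a, b, cols) {
  match(do.call(paste, c(a[cols], sep = "\r")),
        do.call(paste, c(b[cols], sep = "\r")))
}
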