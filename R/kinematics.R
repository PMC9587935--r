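#' Kinematic analysis settings
#'
#' Bundles the tunable parameters of the movement-extraction stage. The
#' velocity threshold (80 mm/s) and FIR cutoff (50 Hz) follow the study's
#' processing pipeline; the minimum segment duration is a standard guard
#' against single-sample noise crossings and is not part of that pipeline.
#'
#' @param cutoff_hz FIR low-pass cutoff frequency, Hz.
#' @param threshold_mm_s Velocity threshold for movement segmentation, mm/s.
#' @param min_duration_ms Minimum duration of a movement segment, ms.
#' @param sound_window_s Two-vector: the sound window in seconds, relative to
#'   delivery onset.
#' @return A list of class `"loc3d_kin_settings"`.
#' @export
kin_settings <- function(cutoff_hz = 50, threshold_mm_s = 80,
                         min_duration_ms = 50, sound_window_s = c(0, 3)) {
  stopifnot(cutoff_hz > 0, threshold_mm_s > 0, min_duration_ms >= 0,
            length(sound_window_s) == 2L, diff(sound_window_s) > 0)
  structure(list(cutoff_hz = cutoff_hz, threshold_mm_s = threshold_mm_s,
                 min_duration_ms = min_duration_ms,
                 sound_window_s = sound_window_s),
            class = "loc3d_kin_settings")
}

#' Zero-phase FIR low-pass filtering of position signals
#'
#' Applies a linear-phase windowed-design FIR low-pass (Hamming window,
#' unit DC gain) forward and backward, giving zero net phase distortion.
#' A cutoff at or above the Nyquist frequency is clamped to 0.45 x the
#' sample rate with a warning: for head data at 100 Hz the nominal 50 Hz
#' cutoff sits exactly at Nyquist, where the filter would be a near no-op.
#'
#' @param x Numeric vector or matrix (columns filtered independently).
#' @param sample_rate Sampling frequency, Hz.
#' @param cutoff Cutoff frequency, Hz (default 50).
#' @param order FIR order (even; default 24, reduced for short series).
#' @return Filtered signal, same shape as `x`.
#' @export
lowpass_filter <- function(x, sample_rate, cutoff = 50, order = 24) {
  xm <- if (is.matrix(x)) x else matrix(x, ncol = 1)
  if (any(!is.finite(xm))) stop("positions must be finite", call. = FALSE)
  nyq <- sample_rate / 2
  if (cutoff >= nyq) {
    cutoff <- 0.45 * sample_rate
    warning(sprintf("cutoff at/above Nyquist; clamped to %.1f Hz", cutoff),
            call. = FALSE)
  }
  n <- nrow(xm)
  if (n < 15L) stop("series too short to filter", call. = FALSE)
  ## filtfilt needs ample padding; shrink the order on short series
  order <- min(order, 2L * ((n %/% 3L - 1L) %/% 2L))
  if (order < 4L) stop("series too short for the FIR order", call. = FALSE)
  fir <- signal::fir1(order, cutoff / nyq, type = "low")
  fir <- fir / sum(fir)  # force exactly unit DC gain
  ## odd-reflection padding suppresses the zero-padding edge transients of
  ## filtfilt on signals with a large DC offset (positions in meters)
  L <- min(3L * order, n - 1L)
  out <- apply(xm, 2, function(col) {
    padded <- c(2 * col[1] - col[(L + 1):2],
                col,
                2 * col[n] - col[(n - 1):(n - L)])
    signal::filtfilt(fir, padded)[(L + 1):(L + n)]
  })
  if (is.matrix(x)) out else as.numeric(out)
}

#' Tangential speed by two-point central differences
#'
#' Computes the speed of a tracked point as the norm of the two-point
#' central-difference derivative of its (filtered) position signal:
#' `v[i] = ||p[i+1] - p[i-1]|| / (2 dt)`, expressed in mm/s. The first and
#' last samples use one-sided differences so the series keeps the source
#' length; they are flagged `central = FALSE`.
#'
#' @param positions Numeric vector (1-D) or n x 3 matrix of positions, meters.
#' @param sample_rate Sampling frequency, Hz.
#' @param t Optional time stamps (seconds); defaults to `(0:(n-1))/sample_rate`.
#' @return A data frame of class `"loc3d_speed_series"` with columns `t`,
#'   `speed` (mm/s, non-negative) and `central` (logical).
#' @export
speed_series <- function(positions, sample_rate, t = NULL) {
  p <- if (is.matrix(positions)) positions else matrix(positions, ncol = 1)
  n <- nrow(p)
  if (n < 3L) stop("at least 3 samples are required", call. = FALSE)
  if (any(!is.finite(p))) stop("positions must be finite", call. = FALSE)
  dt <- 1 / sample_rate
  if (is.null(t)) t <- (seq_len(n) - 1) * dt
  disp <- function(a, b) sqrt(rowSums((p[a, , drop = FALSE] -
                                         p[b, , drop = FALSE])^2))
  v <- numeric(n)
  v[2:(n - 1)] <- disp(3:n, 1:(n - 2)) / (2 * dt)
  v[1] <- disp(2, 1) / dt
  v[n] <- disp(n, n - 1) / dt
  out <- data.frame(t = t, speed = 1000 * v,
                    central = c(FALSE, rep(TRUE, n - 2), FALSE))
  class(out) <- c("loc3d_speed_series", "data.frame")
  out
}

#' Velocity-threshold movement segmentation
#'
#' Detects movements as maximal runs of samples whose speed is at or above
#' the threshold (default 80 mm/s); onset and offset are the first and last
#' sample of the run. Runs shorter than `min_duration_ms` are discarded as
#' noise crossings. The movement count is the number of surviving runs,
#' i.e. the number of times the speed threshold was exceeded.
#'
#' @param speed A [speed_series()] data frame (uniform sampling grid).
#' @param threshold Speed threshold, mm/s.
#' @param min_duration_ms Minimum run duration, ms.
#' @return A data frame with one row per movement: `onset`, `offset` (s),
#'   `peak_speed` (mm/s) and `n_samples`. Zero rows when nothing crosses.
#' @export
segment_movements <- function(speed, threshold = 80, min_duration_ms = 50) {
  stopifnot(is.data.frame(speed), all(c("t", "speed") %in% names(speed)))
  above <- speed$speed >= threshold
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- which(r$values)
  if (length(keep) == 0L)
    return(data.frame(onset = numeric(0), offset = numeric(0),
                      peak_speed = numeric(0), n_samples = integer(0)))
  seg <- data.frame(
    onset = speed$t[starts[keep]],
    offset = speed$t[ends[keep]],
    peak_speed = vapply(keep, function(k)
      max(speed$speed[starts[k]:ends[k]]), numeric(1)),
    n_samples = r$lengths[keep]
  )
  seg <- seg[seg$offset - seg$onset >= min_duration_ms / 1000, , drop = FALSE]
  rownames(seg) <- NULL
  seg
}

#' Head-movement metrics within the sound window
#'
#' Counts the head movements whose onset falls inside the sound window
#' (movements starting after sound offset are excluded) and extracts the
#' first movement's onset and the head facing azimuth at its offset.
#'
#' @param segments Movement segments from [segment_movements()], on a time
#'   axis where t = 0 is the delivery onset.
#' @param head_azimuth Optional data frame `t`, `azimuth` (deg): head facing
#'   direction relative to the delivery-onset reference; used for
#'   `first_end_azimuth`.
#' @param sound_window Two-vector, seconds.
#' @return A list with `n_movements`, `first_onset` (s), `first_end_azimuth`
#'   (deg) and `no_movement` (flag; onset/direction are `NA` when set).
#' @export
head_movement_metrics <- function(segments, head_azimuth = NULL,
                                  sound_window = c(0, 3)) {
  inwin <- segments$onset >= sound_window[1] & segments$onset <= sound_window[2]
  segs <- segments[inwin, , drop = FALSE]
  if (nrow(segs) == 0L)
    return(list(n_movements = 0L, first_onset = NA_real_,
                first_end_azimuth = NA_real_, no_movement = TRUE))
  first <- segs[which.min(segs$onset), ]
  end_az <- NA_real_
  if (!is.null(head_azimuth))
    end_az <- stats::approx(head_azimuth$t, head_azimuth$azimuth,
                            xout = first$offset, rule = 2)$y
  list(n_movements = nrow(segs), first_onset = first$onset,
       first_end_azimuth = end_az, no_movement = FALSE)
}

#' Instruction-compliance check for one trial
#'
#' Trials in which instructions were not followed are rejected: a head
#' movement during sound delivery in the static condition, or an
#' anticipatory hand movement (hand onset before sound offset) in any
#' condition.
#'
#' @param condition `"static"` or `"active"`.
#' @param head_segments,hand_segments Movement segments (delivery-onset time
#'   axis) for the head and hand tracks; pass a zero-row data frame when the
#'   track shows no movements.
#' @param sound_window Two-vector, seconds.
#' @return A list of class `"loc3d_compliance"` with `rejected` (logical) and
#'   `reason` (one of `"anticipatory_hand"`, `"head_move_in_static"`,
#'   `"none"`).
#' @export
check_compliance <- function(condition, head_segments, hand_segments,
                             sound_window = c(0, 3)) {
  if (!condition %in% c("static", "active"))
    stop("condition must be 'static' or 'active'", call. = FALSE)
  if (is.null(head_segments) || is.null(hand_segments))
    stop("head and hand movement segments are both required", call. = FALSE)
  reason <- "none"
  if (condition == "static" &&
      any(head_segments$onset > sound_window[1] &
            head_segments$onset < sound_window[2]))
    reason <- "head_move_in_static"
  else if (any(hand_segments$onset < sound_window[2]))
    reason <- "anticipatory_hand"
  structure(list(rejected = reason != "none", reason = reason),
            class = "loc3d_compliance")
}

#' Interquartile-range outlier rule
#'
#' Flags per-participant values outside `[Q1 - 1.5 IQR, Q3 + 1.5 IQR]`
#' (closed interval), the rule used to exclude participants who made almost
#' no head movements in the active condition. Quartiles use linear
#' interpolation (`stats::quantile` type 7).
#'
#' @param x Numeric vector (at least 4 values).
#' @return A logical vector flagging the outliers, with the interval in
#'   attribute `"bounds"`.
#' @export
#' @examples
#' detect_movement_outliers(c(70, 75, 80, 72, 74, 0))
detect_movement_outliers <- function(x) {
  if (length(x) < 4L)
    stop("at least 4 values are required for the IQR rule", call. = FALSE)
  q <- stats::quantile(x, c(0.25, 0.75), names = FALSE, na.rm = TRUE)
  iqr <- q[2] - q[1]
  bounds <- c(q[1] - 1.5 * iqr, q[2] + 1.5 * iqr)
  out <- x < bounds[1] | x > bounds[2]
  attr(out, "bounds") <- bounds
  out
}
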