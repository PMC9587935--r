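test_that("zero-phase FIR filter has unit DC gain and removes high frequencies", {
  fs <- 200
  t <- seq(0, 2, by = 1 / fs)
  const <- rep(0.73, length(t))
  expect_lt(max(abs(lowpass_filter(const, fs, 50) - const)), 1e-9)

  ## 2 Hz sinusoid passes a 45 Hz cutoff essentially unattenuated
  s <- sin(2 * pi * 2 * t)
  out <- lowpass_filter(s, fs, 45)
  mid <- seq(50, length(t) - 50)
  expect_lt(max(abs(out[mid] - s[mid])) / max(abs(s)), 0.01)

  ## broadband noise loses variance above the cutoff
  set.seed(3)
  w <- rnorm(length(t))
  expect_lt(var(lowpass_filter(w, fs, 20)), var(w))

  expect_warning(lowpass_filter(w, 100, 50), "Nyquist")
  expect_error(lowpass_filter(rnorm(5), 100, 20), "short")
})

test_that("central-difference speed is exact for linear and quadratic motion", {
  fs <- 100
  t <- seq(0, 2, by = 1 / fs)
  ## straight line at 0.1 m/s -> 100 mm/s at interior samples
  lin <- cbind(0.1 * t, 0, 0)
  v <- speed_series(lin, fs)
  expect_equal(v$speed[v$central], rep(100, sum(v$central)))
  ## stationary track -> identically zero
  expect_true(all(speed_series(cbind(0 * t, 1, 2), fs)$speed == 0))
  ## p(t) = t^2: the two-point central difference is exact for quadratics
  quad <- matrix(t^2, ncol = 1)
  v2 <- speed_series(quad, fs)
  expect_equal(v2$speed[v2$central], 1000 * abs(2 * t[v2$central]),
               tolerance = 1e-9)
  expect_error(speed_series(cbind(1:2, 0, 0), fs), "3 samples")
})

test_that("filtering then differentiating preserves slope of a linear track", {
  fs <- 100
  t <- seq(0, 3, by = 1 / fs)
  p <- cbind(0.25 * t, -0.1 * t, 0.05 * t)
  f <- suppressWarnings(lowpass_filter(p, fs, 50))
  v <- speed_series(f, fs)
  slope <- 1000 * sqrt(0.25^2 + 0.1^2 + 0.05^2)
  mid <- seq(40, length(t) - 40)
  expect_lt(max(abs(v$speed[mid] - slope)), 1e-6)
})

test_that("velocity-threshold segmentation finds constructed movements", {
  fs <- 100
  ## everywhere below threshold
  slow <- bell_track(1, 3, 0.05, fs)  # peak ~47 mm/s
  empty <- segment_movements(speed_series(matrix(slow$p), fs, slow$t))
  expect_equal(nrow(empty), 0L)

  ## one bell above 80 mm/s: onset/offset at the crossing samples
  b <- bell_track(1.0, 1.4, 0.08, fs)  # peak 1.875*0.08/0.4 = 375 mm/s
  sp <- speed_series(matrix(b$p), fs, b$t)
  seg <- segment_movements(sp, threshold = 80)
  expect_equal(nrow(seg), 1L)
  ## crossings located by direct scan of the speed series (oracle)
  above <- which(sp$speed >= 80)
  expect_equal(seg$onset, sp$t[min(above)])
  expect_equal(seg$offset, sp$t[max(above)])
  expect_gte(seg$peak_speed, 80)
  expect_gt(seg$peak_speed, 300)

  ## two well-separated bells, in time order
  b2 <- bell_track(3.0, 3.5, -0.06, fs)
  two <- segment_movements(speed_series(matrix(b$p + b2$p), fs, b$t))
  expect_equal(nrow(two), 2L)
  expect_lt(two$offset[1], two$onset[2])

  ## single-sample blip is discarded by the minimum-duration rule
  blip <- sp
  blip$speed[] <- 0
  blip$speed[200] <- 500
  expect_equal(nrow(segment_movements(blip, 80, min_duration_ms = 50)), 0L)
  expect_equal(nrow(segment_movements(blip, 80, min_duration_ms = 0)), 1L)
})

test_that("raising the threshold never increases the segment count", {
  fs <- 100
  set.seed(9)
  for (i in 1:10) {
    k <- sample(1:4, 1)
    p <- numeric(501)
    for (j in seq_len(k))
      p <- p + bell_track(0.4 + (j - 1) * 1.1, 0.9 + (j - 1) * 1.1,
                          runif(1, 0.05, 0.12), fs)$p
    sp <- speed_series(matrix(p), fs)
    counts <- vapply(c(40, 80, 150, 300, 1000),
                     function(th) nrow(segment_movements(sp, th)), integer(1))
    expect_true(all(diff(counts) <= 0))
    ## exact count at the default threshold on the noiseless profile
    expect_equal(nrow(segment_movements(sp, 80)), k)
  }
})

test_that("head-movement metrics apply the sound-window rule", {
  segs <- data.frame(onset = c(1.1, 3.1), offset = c(1.4, 3.4),
                     peak_speed = c(300, 250), n_samples = c(31, 31))
  m <- head_movement_metrics(segs, sound_window = c(0, 3))
  expect_equal(m$n_movements, 1L)
  expect_equal(m$first_onset, 1.1)

  none <- head_movement_metrics(segs[0, ])
  expect_equal(none$n_movements, 0L)
  expect_true(none$no_movement)
  expect_true(is.na(none$first_onset))

  az <- data.frame(t = seq(0, 4, 0.01), azimuth = pmin(30, seq(0, 4, 0.01) * 25))
  m2 <- head_movement_metrics(segs, head_azimuth = az, sound_window = c(0, 3))
  expect_equal(m2$first_end_azimuth, 30, tolerance = 1e-6)
})

test_that("compliance check rejects the instructed-violation patterns", {
  no_seg <- data.frame(onset = numeric(0), offset = numeric(0))
  hand_late <- data.frame(onset = 3.4, offset = 4.1)
  hand_early <- data.frame(onset = 2.0, offset = 2.7)
  head_move <- data.frame(onset = 1.5, offset = 1.9)

  ok <- check_compliance("static", no_seg, hand_late)
  expect_false(ok$rejected)
  expect_equal(ok$reason, "none")

  r1 <- check_compliance("static", head_move, hand_late)
  expect_true(r1$rejected)
  expect_equal(r1$reason, "head_move_in_static")

  r2 <- check_compliance("active", head_move, hand_early)
  expect_true(r2$rejected)
  expect_equal(r2$reason, "anticipatory_hand")

  ## head movements are legitimate in active listening
  expect_false(check_compliance("active", head_move, hand_late)$rejected)
  expect_error(check_compliance("sitting", no_seg, hand_late), "condition")
  expect_error(check_compliance("static", NULL, hand_late), "required")
})

test_that("IQR outlier rule flags near-zero movers", {
  x <- c(70, 75, 80, 72, 74, 0)
  fl <- detect_movement_outliers(x)
  expect_equal(which(fl), 6L)
  ## quartile oracle with the same (type 7) convention
  q <- quantile(x, c(0.25, 0.75), names = FALSE)
  expect_equal(attr(fl, "bounds"), c(q[1] - 1.5 * diff(q), q[2] + 1.5 * diff(q)))

  expect_false(any(detect_movement_outliers(rep(50, 6))))

  ## a 6.3% mover among typical 70-100% movers is excluded
  cohort <- c(88, 95, 72, 100, 81, 77, 92, 6.3)
  expect_true(detect_movement_outliers(cohort)[8])
  expect_error(detect_movement_outliers(c(1, 2, 3)), "4 values")
})
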