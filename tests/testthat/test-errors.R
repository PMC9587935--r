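test_that("per-dimension errors use circular azimuth differences", {
  ## response az 20 vs target 30 at 55 cm
  r1 <- spherical_to_cartesian(20, 0, 55)
  t1 <- spherical_to_cartesian(30, 0, 55)
  ## wrap-around: response 175 vs target -175
  r2 <- spherical_to_cartesian(175, 0, 55)
  t2 <- spherical_to_cartesian(-175, 0, 55)
  ## depth error: response 60.2 cm vs target 55 cm
  r3 <- spherical_to_cartesian(0, 0, 60.2)
  t3 <- spherical_to_cartesian(0, 0, 55)
  rec <- make_records(rbind(r1, r2, r3), rbind(t1, t2, t3),
                      position_az = c(30, -150, 30),
                      position_depth_cm = c(55, 55, 55))
  out <- dimension_errors(rec)
  expect_equal(out$az_signed[1], -10, tolerance = 1e-9)
  expect_equal(out$az_abs[1], 10, tolerance = 1e-9)
  ## circular-difference oracle: smallest |d + k*360| over candidate shifts
  cand <- 175 - (-175) + c(-360, 0, 360)
  expect_equal(out$az_signed[2], cand[which.min(abs(cand))], tolerance = 1e-9)
  expect_equal(out$az_abs[2], 10, tolerance = 1e-9)
  expect_equal(out$depth_signed_cm[3], 5.2, tolerance = 1e-9)

  ## degenerate zero-depth response is flagged
  rec0 <- make_records(matrix(0, 1, 3), t1, 30, 55)
  expect_true(dimension_errors(rec0)$degenerate)
})

test_that("variable error is the per-position SD averaged across positions", {
  ## two positions: identical responses at one, {25, 35} degrees at the other
  r <- rbind(spherical_to_cartesian(30, 0, 55),
             spherical_to_cartesian(30, 0, 55),
             spherical_to_cartesian(25, 0, 35),
             spherical_to_cartesian(35, 0, 35))
  tg <- rbind(spherical_to_cartesian(30, 0, 55),
              spherical_to_cartesian(30, 0, 55),
              spherical_to_cartesian(30, 0, 35),
              spherical_to_cartesian(30, 0, 35))
  rec <- dimension_errors(make_records(r, tg, c(30, 30, 30, 30),
                                       c(55, 55, 35, 35)))
  ve <- variable_error(rec, "response_az", "participant", circular = TRUE)
  ## sample SD of {25, 35} is 7.0711; mean with the zero-SD position
  expect_equal(ve$variable_error, mean(c(0, sd(c(25, 35)))), tolerance = 1e-6)
  expect_equal(ve$n_positions, 2)

  ## positions with SDs 4 and 6 average to 5
  set.seed(1)
  mk <- function(vals, d) t(vapply(vals, function(a)
    spherical_to_cartesian(a, 0, d), numeric(3)))
  v1 <- c(26, 34); v2 <- c(27, 33)  # SDs 5.657, 4.243
  rec2 <- dimension_errors(make_records(
    rbind(mk(v1, 55), mk(v2, 35)),
    rbind(mk(c(30, 30), 55), mk(c(30, 30), 35)),
    rep(30, 4), c(55, 55, 35, 35)))
  ve2 <- variable_error(rec2, "response_az", "participant", circular = TRUE)
  expect_equal(ve2$variable_error, mean(c(sd(v1), sd(v2))), tolerance = 1e-6)

  ## a single-trial position is skipped with a warning
  rec3 <- rec[1:3, ]
  expect_warning(variable_error(rec3, "response_az", "participant"), "skipped")
})

test_that("3D error index matches hand-computed cases and its algebra", {
  ## all responses at the target: everything zero
  tg <- rbind(spherical_to_cartesian(30, 0, 55), spherical_to_cartesian(30, 0, 55))
  rec0 <- make_records(tg, tg, c(30, 30), c(55, 55))
  z <- error_3d(rec0)
  expect_equal(z$C_bar, 0)
  expect_equal(z$s_bar, 0)
  expect_equal(z$error_3d, 0)

  ## constant 10 cm offset with no spread: the formula collapses to C_bar
  off <- make_records(tg + matrix(c(0.1, 0, 0), 2, 3, byrow = TRUE), tg,
                      c(30, 30), c(55, 55))
  cst <- error_3d(off)
  expect_equal(cst$C_bar, 10, tolerance = 1e-9)
  expect_equal(cst$s_bar, 0, tolerance = 1e-9)
  expect_equal(cst$error_3d, 10, tolerance = 1e-9)

  ## two trials at one position: responses (0,0,0) and (0,0.06,0) m against
  ## target (0,0.03,0) m. Hand computation: C_i = {3, 3} cm so C_bar = 3;
  ## RMS dispersion = sqrt(var_y) = sqrt(18) cm; error_3d = sqrt(9 + 18)
  hc <- make_records(rbind(c(0, 0, 0), c(0, 0.06, 0)),
                     rbind(c(0, 0.03, 0), c(0, 0.03, 0)), c(0, 0), c(55, 55))
  h <- error_3d(hc, dispersion = "rms3d")
  expect_equal(h$C_bar, 3, tolerance = 1e-9)
  expect_equal(h$s_bar, sqrt(18), tolerance = 1e-9)
  expect_equal(h$error_3d, sqrt(27), tolerance = 1e-9)
  ## per-axis-mean dispersion alternative on the same data
  h2 <- error_3d(hc, dispersion = "axis_mean")
  expect_equal(h2$s_bar, sqrt(18) / 3, tolerance = 1e-9)

  expect_error(error_3d(hc[0, ]), "no accepted trials")
})

test_that("error_3d dominates its components and Jensen holds on cohorts", {
  coh <- generate_experiment(loc3d_config(n_participants = 5, seed = 13))
  run <- run_pipeline(coh)
  e3 <- run$error3d
  expect_true(all(e3$error_3d >= e3$C_bar - 1e-12))
  expect_true(all(e3$error_3d >= e3$s_bar - 1e-12))
  expect_equal(e3$error_3d, sqrt(e3$C_bar^2 + e3$s_bar^2))
  ang <- run$participant_errors$angular
  expect_true(all(ang$az_abs >= abs(ang$az_signed) - 1e-12))
  expect_true(all(ang$el_abs >= abs(ang$el_signed) - 1e-12))
})

test_that("placement accuracy recovers known offsets and the noise law", {
  tr0 <- data.frame(ph_x = c(0, 0.1), ph_y = c(0.5, 0.5), ph_z = 0,
                    ah_x = c(0, 0.1), ah_y = c(0.5, 0.5), ah_z = 0)
  p0 <- placement_accuracy(tr0)
  expect_equal(unname(p0$per_axis_cm), c(0, 0, 0))
  expect_equal(p0$norm_3d_cm, 0)

  tr1 <- tr0
  tr1$ah_x <- tr1$ah_x + 0.01
  p1 <- placement_accuracy(tr1)
  expect_equal(unname(p1$per_axis_cm), c(1, 0, 0))
  expect_equal(p1$norm_3d_cm, 1)

  ## Monte-Carlo oracle for the generator's placement-noise law
  cfg <- loc3d_config(n_participants = 6, seed = 17)
  run <- placement_accuracy(generate_experiment(cfg)$trials)
  set.seed(99)
  N <- 40000
  v <- cbind(rnorm(N, 0, cfg$placement_direction_sd[1]),
             rnorm(N, 0, cfg$placement_direction_sd[2]),
             rnorm(N, 0, cfg$placement_direction_sd[3]))
  u <- v / sqrt(rowSums(v^2))
  r <- cfg$placement_tolerance_cm *
    rbeta(N, cfg$placement_radius_beta[1], cfg$placement_radius_beta[2])
  oracle <- u * r
  expect_equal(run$norm_3d_cm, mean(r), tolerance = 0.03)
  expect_equal(unname(run$per_axis_cm), colMeans(abs(oracle)), tolerance = 0.05)
})
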