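test_that("default design yields the full balanced block structure", {
  coh <- generate_experiment(loc3d_config(n_participants = 1, seed = 2))
  tr <- coh$trials
  expect_equal(nrow(tr), 192L)
  expect_equal(as.vector(table(tr$block)), rep(48L, 4))
  ## each of the 12 positions appears 8 times per condition
  tab <- table(tr$position_az, tr$position_depth_cm, tr$condition)
  expect_true(all(tab == 8L))
  ## ABBA counterbalance across participants
  coh2 <- generate_experiment(loc3d_config(n_participants = 2, seed = 2))
  seqs <- with(coh2$trials, tapply(condition, list(participant, block),
                                   function(x) unique(x)))
  expect_equal(unname(seqs[1, ]), c("active", "static", "static", "active"))
  expect_equal(unname(seqs[2, ]), c("static", "active", "active", "static"))
})

test_that("generation is deterministic in the seed and leaves the RNG alone", {
  cfg <- loc3d_config(n_participants = 2, seed = 9)
  a <- generate_experiment(cfg)
  set.seed(1234)
  probe <- runif(1)
  b <- generate_experiment(cfg)
  expect_identical(a$trials, b$trials)
  expect_identical(a$ground_truth, b$ground_truth)
  ## caller RNG stream is restored around generation
  set.seed(1234)
  expect_identical(runif(1), probe)
  c2 <- generate_experiment(loc3d_config(n_participants = 2, seed = 10))
  expect_false(identical(a$trials$rx, c2$trials$rx))
})

test_that("zero-noise zero-bias responses hit the predetermined targets", {
  cfg <- loc3d_config(n_participants = 2, seed = 4, noise_scale = 0,
                      bias_scale = 0, placement_scale = 0)
  coh <- generate_experiment(cfg)
  tr <- coh$trials
  expect_equal(tr$ah_x, tr$ph_x)
  expect_lt(max(abs(c(tr$rx - tr$ph_x, tr$ry - tr$ph_y, tr$rz - tr$ph_z))), 1e-12)
  run <- run_pipeline(coh)
  expect_lt(max(abs(run$records$az_abs)), 1e-9)
  expect_lt(max(abs(run$records$depth_abs_cm)), 1e-9)
  expect_lt(max(run$error3d$error_3d), 1e-9)
})

test_that("speaker placement never leaves the tolerance sphere", {
  coh <- generate_experiment(loc3d_config(n_participants = 3, seed = 6))
  d <- 100 * sqrt((coh$trials$ah_x - coh$trials$ph_x)^2 +
                    (coh$trials$ah_y - coh$trials$ph_y)^2 +
                    (coh$trials$ah_z - coh$trials$ph_z)^2)
  expect_true(all(d <= 2.5))
  expect_gt(mean(d), 1.5)  # boundary-hugging placement law
})

test_that("movement ground truth respects its own bookkeeping", {
  coh <- generate_experiment(loc3d_config(n_participants = 4, seed = 12))
  gt <- coh$ground_truth
  expect_equal(nrow(gt), nrow(coh$trials))
  expect_true(all(gt$n_in_window <= gt$n_movements))
  expect_true(all(gt$moved[gt$condition == "static"] == FALSE))
  expect_true(all(is.na(gt$first_onset_s) | gt$first_onset_s >= 0))
  expect_true(all((gt$compliance_reason != "none") ==
                    (gt$anticipatory | gt$static_head_violation)))
  ## front-space first movements aim near the target azimuth
  fr <- gt[gt$moved & gt$sector == "front" & !is.na(gt$first_end_azimuth), ]
  expect_gt(cor(fr$first_end_azimuth,
                coh$trials$position_az[match(paste(fr$participant, fr$trial),
                                             paste(coh$trials$participant,
                                                   coh$trials$trial))]), 0.9)
})

test_that("stimulus envelope follows the modulation depth", {
  set.seed(3)
  x <- generate_stimulus(3.0, 0.8, sample_rate = 44100)
  expect_length(x, 132300L)
  env <- attr(x, "envelope")
  expect_equal(min(env), 0.2, tolerance = 1e-6)
  expect_equal(max(env), 1.0, tolerance = 1e-6)
  expect_lte(max(abs(x)), 1)

  ## windowed RMS tracks the envelope within a few percent
  win <- function(w, k) sqrt(mean(w[k]^2))
  fs <- 44100
  hi <- which.max(env[1:fs])
  lo <- which.min(env[1:fs])
  idx <- function(i) max(1, i - 500):min(length(x), i + 500)
  ratio <- win(x, idx(lo)) / win(x, idx(hi))
  expect_equal(ratio, 0.2, tolerance = 0.1)

  ## zero depth: flat envelope, stationary RMS
  x0 <- generate_stimulus(1, 0, sample_rate = 8000)
  r1 <- win(x0, 1:2000); r2 <- win(x0, 4001:6000)
  expect_equal(r1 / r2, 1, tolerance = 0.1)
  expect_error(generate_stimulus(3, 1.2), "mod_depth")
})

test_that("the WAV writer emits a valid RIFF/PCM16 header", {
  x <- generate_stimulus(0.1, 0.8, sample_rate = 8000)
  f <- tempfile(fileext = ".wav")
  write_wav(x, f)
  expect_equal(file.size(f), 44 + 2 * length(x))
  con <- file(f, "rb")
  on.exit(close(con))
  expect_equal(readChar(con, 4), "RIFF")
  invisible(readBin(con, "integer", 1, size = 4, endian = "little"))
  expect_equal(readChar(con, 8), "WAVEfmt ")
  expect_equal(readBin(con, "integer", 1, size = 4, endian = "little"), 16L)
  expect_equal(readBin(con, "integer", 2, size = 2, endian = "little"),
               c(1L, 1L))  # PCM, mono
  expect_equal(readBin(con, "integer", 1, size = 4, endian = "little"), 8000L)
})

test_that("invalid generator configurations are rejected", {
  expect_error(loc3d_config(anticipatory_rate = c(static = 1.2, active = 0.1)),
               "\\[0, 1\\]")
  expect_error(loc3d_config(n_participants = 0))
  expect_error(loc3d_config(trials_per_cell = 0))
})
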