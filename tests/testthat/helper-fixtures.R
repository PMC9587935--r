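# shared fixture builders (everything generated in code)

# a bell-shaped (minimum-jerk-like) speed profile track: 1-D position that
# moves `dist` meters between t_on and t_off, sampled at fs
bell_track <- function(t_on, t_off, dist, fs = 100, t_max = 5) {
  t <- seq(0, t_max, by = 1 / fs)
  tau <- pmin(1, pmax(0, (t - t_on) / (t_off - t_on)))
  s <- 10 * tau^3 - 15 * tau^4 + 6 * tau^5
  list(t = t, p = dist * s)
}

# response records at given nominal positions, one row per trial
make_records <- function(resp, targ, position_az, position_depth_cm,
                         participant = "P01", condition = "static") {
  resp <- rbind(resp)
  targ <- rbind(targ)
  stopifnot(nrow(resp) == nrow(targ))
  data.frame(participant = participant, condition = condition,
             sector = ifelse(abs(position_az) < 90, "front", "back"),
             distance = c(near = "near", middle = "middle",
                          far = "far")[match(position_depth_cm, c(35, 55, 75))],
             position_az = position_az, position_depth_cm = position_depth_cm,
             rx = resp[, 1], ry = resp[, 2], rz = resp[, 3],
             tx = targ[, 1], ty = targ[, 2], tz = targ[, 3],
             stringsAsFactors = FALSE)
}

# random unit quaternion
random_quat <- function() {
  q <- rnorm(4)
  q / sqrt(sum(q^2))
}

# independent rotation-matrix oracle built element-wise from a quaternion
# (kept separate from the package's implementation on purpose)
oracle_rotmat <- function(q) {
  w <- q[1]; x <- q[2]; y <- q[3]; z <- q[4]
  rbind(c(w^2 + x^2 - y^2 - z^2, 2 * (x * y - w * z), 2 * (x * z + w * y)),
        c(2 * (x * y + w * z), w^2 - x^2 + y^2 - z^2, 2 * (y * z - w * x)),
        c(2 * (x * z - w * y), 2 * (y * z + w * x), w^2 - x^2 - y^2 + z^2))
}

# brute-force Holm step-down enumeration
oracle_holm <- function(p) {
  n <- length(p)
  o <- order(p)
  adj <- numeric(n)
  running <- 0
  for (i in seq_len(n)) {
    running <- max(running, (n - i + 1) * p[o[i]])
    adj[o[i]] <- min(1, running)
  }
  adj
}

# brute-force Kendall tau-b over all pairs, with tie correction
oracle_tau_b <- function(x, y) {
  n <- length(x)
  conc <- disc <- tx <- ty <- 0
  for (i in 1:(n - 1)) for (j in (i + 1):n) {
    dx <- x[j] - x[i]; dy <- y[j] - y[i]
    if (dx == 0 && dy == 0) { tx <- tx + 1; ty <- ty + 1 }
    else if (dx == 0) tx <- tx + 1
    else if (dy == 0) ty <- ty + 1
    else if (dx * dy > 0) conc <- conc + 1
    else disc <- disc + 1
  }
  n0 <- n * (n - 1) / 2
  (conc - disc) / sqrt((n0 - tx) * (n0 - ty))
}
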