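test_that("repeated-measures ANOVA agrees with paired-t closed forms", {
  set.seed(21)
  n <- 12
  d <- expand.grid(id = sprintf("s%02d", 1:n), cond = c("a", "b"),
                   stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d)) + 0.8 * (d$cond == "b") + rep(rnorm(n), 2)
  a <- rm_anova(d, "y", "id", "cond")
  tt <- t.test(d$y[d$cond == "a"], d$y[d$cond == "b"], paired = TRUE)
  expect_equal(a$F, unname(tt$statistic)^2, tolerance = 1e-9)
  expect_equal(a$p, tt$p.value, tolerance = 1e-9)
  expect_equal(a$df1, 1)
  expect_equal(a$df2, n - 1)

  ## zero effect: identical condition means for each participant
  d0 <- d
  base <- rnorm(n)
  d0$y <- base[match(d0$id, sprintf("s%02d", 1:n))]
  a0 <- rm_anova(d0, "y", "id", "cond")
  expect_equal(a0$F, 0, tolerance = 1e-12)
})

test_that("2x2 within ANOVA matches difference-score t oracles", {
  set.seed(31)
  n <- 10
  d <- expand.grid(id = sprintf("s%02d", 1:n), A = c("a1", "a2"),
                   B = c("b1", "b2"), stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d)) + (d$A == "a2") * 0.5 + (d$A == "a2") * (d$B == "b2")
  a <- rm_anova(d, "y", "id", c("A", "B"))

  ## oracle: each 1-df within effect equals the square of a paired /
  ## one-sample t on the participant contrast scores
  wide <- function(A, B) d$y[d$A == A & d$B == B][match(1:n, as.integer(factor(d$id[d$A == A & d$B == B])))]
  y11 <- wide("a1", "b1"); y12 <- wide("a1", "b2")
  y21 <- wide("a2", "b1"); y22 <- wide("a2", "b2")
  tA <- t.test((y21 + y22) / 2 - (y11 + y12) / 2)
  tB <- t.test((y12 + y22) / 2 - (y11 + y21) / 2)
  tAB <- t.test((y22 - y21) - (y12 - y11))
  expect_equal(a$F[a$term == "A"], unname(tA$statistic)^2, tolerance = 1e-9)
  expect_equal(a$F[a$term == "B"], unname(tB$statistic)^2, tolerance = 1e-9)
  expect_equal(a$F[a$term == "A:B"], unname(tAB$statistic)^2, tolerance = 1e-9)
  expect_equal(a$p[a$term == "A"], tA$p.value, tolerance = 1e-9)
  ## effect sizes are proportions in [0, 1]
  expect_true(all(a$ges >= 0 & a$ges <= 1))
})

test_that("Greenhouse-Geisser correction applies to multi-level factors only", {
  set.seed(41)
  n <- 14
  d <- expand.grid(id = sprintf("s%02d", 1:n), dist = c("near", "middle", "far"),
                   stringsAsFactors = FALSE)
  ## heterogeneous covariance structure to violate sphericity
  sub <- rnorm(n)
  d$y <- sub[match(d$id, sprintf("s%02d", 1:n))] +
    c(near = 0, middle = 2, far = 2.5)[d$dist] +
    rnorm(nrow(d), 0, c(near = 0.3, middle = 1.5, far = 3)[d$dist])
  a <- rm_anova(d, "y", "id", "dist")
  expect_equal(a$correction, "GG")
  expect_gte(a$gg_epsilon, 1 / 2)
  expect_lte(a$gg_epsilon, 1)
  expect_lt(a$gg_epsilon, 1)           # this structure violates sphericity
  expect_lte(a$df1_gg, a$df1)
  expect_lte(a$df2_gg, a$df2)
  expect_gte(a$p_gg, a$p)              # correction can only weaken evidence

  ## epsilon oracle: eigenvalues of the double-centered covariance
  wide <- sapply(c("near", "middle", "far"), function(l)
    d$y[d$dist == l][match(1:n, as.integer(factor(d$id[d$dist == l])))])
  S <- cov(wide)
  k <- 3
  C <- diag(k) - 1 / k
  lam <- eigen(C %*% S %*% C, symmetric = TRUE)$values[1:(k - 1)]
  eps_oracle <- sum(lam)^2 / ((k - 1) * sum(lam^2))
  expect_equal(a$gg_epsilon, eps_oracle, tolerance = 1e-8)

  ## two-level factors are sphericity-trivial
  d2 <- d[d$dist != "far", ]
  expect_equal(rm_anova(d2, "y", "id", "dist")$correction, "none")
})

test_that("ANOVA validates its design", {
  d <- expand.grid(id = c("s1", "s2", "s3"), cond = c("a", "b"),
                   stringsAsFactors = FALSE)
  d$y <- rnorm(6)
  expect_error(rm_anova(d[-1, ], "y", "id", "cond"), "missing cells")
  expect_error(rm_anova(d[d$id != "s3", ], "y", "id", "cond"), "3 participants")
})

test_that("Holm adjustment matches step-down enumeration", {
  expect_equal(holm_adjust(0.03), 0.03)
  expect_equal(holm_adjust(c(0.01, 0.04)), c(0.02, 0.04))
  expect_equal(holm_adjust(c(0.03, 0.03, 0.03)), c(0.09, 0.09, 0.09))
  set.seed(5)
  for (i in 1:20) {
    p <- runif(sample(2:5, 1))^2
    adj <- holm_adjust(p)
    expect_equal(adj, oracle_holm(p))
    expect_true(all(adj >= p))
    expect_equal(order(adj), order(adj[order(p)][rank(p)]))  # order-preserving
    expect_true(all(diff(adj[order(p)]) >= -1e-15))
  }
  expect_error(holm_adjust(c(0.2, 1.4)), "0, 1")
})

test_that("Kendall correlation matches brute-force pair counting", {
  up <- kendall_correlation(1:6, c(2, 3, 5, 7, 11, 13))
  expect_equal(up$value, 1)
  expect_equal(kendall_correlation(c(1, 2, 3), c(1, 3, 2))$value, 1 / 3,
               tolerance = 1e-12)
  expect_equal(kendall_correlation(1:5, 5:1)$value, -1)
  set.seed(8)
  for (i in 1:15) {
    x <- sample(1:4, 8, replace = TRUE)   # ties included
    y <- sample(1:4, 8, replace = TRUE)
    if (sd(x) == 0 || sd(y) == 0) next
    expect_equal(kendall_correlation(x, y)$value, oracle_tau_b(x, y),
                 tolerance = 1e-12)
  }
  expect_error(kendall_correlation(rep(1, 5), 1:5), "zero variance")
})

test_that("condition contrasts handle degenerate pairs and report means", {
  d <- expand.grid(id = sprintf("s%d", 1:8), condition = c("active", "static"),
                   sector = c("front", "back"), stringsAsFactors = FALSE)
  d$y <- rnorm(nrow(d))
  ## identical paired samples: difference 0, p = 1
  d0 <- d
  d0$y <- rep(rnorm(16), 2)[order(rep(1:2, each = 16))]
  d0$y[d0$condition == "static"] <- d0$y[d0$condition == "active"]
  c0 <- condition_contrast(d0, "y", "id", "condition", by = "sector")
  expect_equal(c0$diff, c(0, 0))
  expect_equal(c0$p, c(1, 1))

  ## constant non-zero shift: zero-variance differences, flagged
  dc <- d
  dc$y[dc$condition == "static"] <- dc$y[dc$condition == "active"] + 2
  cc <- condition_contrast(dc, "y", "id", "condition", by = "sector")
  expect_true(all(cc$degenerate))
  expect_true(all(is.na(cc$p)))

  ## agreement with t.test and Holm family across strata
  cr <- condition_contrast(d, "y", "id", "condition", by = "sector")
  expect_equal(cr$p_holm, holm_adjust(cr$p))
  for (s in c("front", "back")) {
    v1 <- d$y[d$condition == "active" & d$sector == s]
    v2 <- d$y[d$condition == "static" & d$sector == s]
    tt <- t.test(v1, v2, paired = TRUE)
    expect_equal(cr$p[cr$stratum == s], tt$p.value, tolerance = 1e-12)
  }
  expect_error(condition_contrast(d[-1, ], "y", "id", "condition", by = "sector"),
               "unpaired")
})

test_that("paired-contrast power tracks the closed-form prediction", {
  set.seed(55)
  n <- 20; nrep <- 400; delta <- 1  # shift of one SD of the differences
  rej <- 0
  for (r in seq_len(nrep)) {
    base <- rnorm(n)
    d <- data.frame(id = rep(sprintf("s%d", 1:n), 2),
                    condition = rep(c("a", "b"), each = n),
                    y = c(base, base + rnorm(n, delta, 1)))  # differences ~ N(delta, 1)
    cr <- condition_contrast(d, "y", "id", "condition")
    rej <- rej + (cr$p < 0.05)
  }
  power_mc <- rej / nrep
  power_exact <- power.t.test(n = n, delta = delta, sd = 1, type = "paired",
                              sig.level = 0.05)$power
  expect_lt(abs(power_mc - power_exact), 3 * sqrt(power_exact * (1 - power_exact) / nrep))
})
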