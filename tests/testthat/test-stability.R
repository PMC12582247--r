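test_that("return map on a noiseless AR(1) recovers the coefficient exactly", {
  lam <- 0.5
  x <- numeric(80); x[1] <- 1
  for (i in 2:80) x[i] <- lam * x[i - 1]
  dev <- make_dev(x, dp_y = rnorm(80))
  rm1 <- fit_return_map(dev, 0.75, leg = "L")
  expect_equal(rm1$spectral_radius, lam, tolerance = 1e-10)
  # generating-matrix property with two independent channels
  y <- numeric(80); y[1] <- -2
  for (i in 2:80) y[i] <- -0.3 * y[i - 1]
  dev2 <- make_dev(x, dp_y = rnorm(80), extra_channels = list(body_x_pos = y))
  rm2 <- fit_return_map(dev2, 0.75, leg = "L")
  expect_equal(sort(Mod(rm2$eigenvalues)), c(0.3, 0.5), tolerance = 1e-8)
})

test_that("forward and backward return maps are both available and differ", {
  set.seed(30)
  n <- 400
  x <- as.numeric(arima.sim(list(ar = 0.5), n))
  dev <- make_dev(x, dp_y = rnorm(n))
  fwd <- fit_return_map(dev, 0.75, leg = "L", direction = "forward")
  bwd <- fit_return_map(dev, 0.75, leg = "L", direction = "backward")
  expect_equal(fwd$spectral_radius, 0.5, tolerance = 0.15)
  # under noise the backward fit is not the reciprocal of the forward one
  expect_false(isTRUE(all.equal(bwd$spectral_radius,
                                1 / fwd$spectral_radius, tolerance = 0.2)))
  expect_equal(bwd$spectral_radius, 0.5, tolerance = 0.15)
})

test_that("return map pairs never span bout boundaries", {
  # two bouts whose concatenation would fake a huge coefficient
  x1 <- rep(c(1, -1), 20) * 1e-3
  x2 <- rep(c(1, -1), 20) * 1e-3 + 5
  d1 <- make_dev(x1, dp_y = rnorm(40), bout = "b1")
  d2 <- make_dev(x2, dp_y = rnorm(40), bout = "b2")
  dev <- d1
  dev$meta <- rbind(d1$meta, d2$meta)
  dev$dQ <- array(NA_real_, c(80, 5, 1), dimnames = dimnames(d1$dQ))
  dev$dQ[1:40, , ] <- d1$dQ
  dev$dQ[41:80, , ] <- d2$dQ
  dev$dQt <- array(rnorm(80 * 5 * 4), c(80, 5, 4),
                   dimnames = dimnames(d1$dQt))
  rm1 <- fit_return_map(dev, 0.75, leg = "L")
  expect_equal(rm1$n_pairs, 78)   # 39 within each bout, none across
  expect_equal(rm1$spectral_radius, 1, tolerance = 0.05) # alternating sign map
})

test_that("lag correlations follow closed forms", {
  set.seed(31)
  # iid: r(N) ~ 0 for N >= 1; r(0) = 1 by construction
  iid <- lapply(1:4, function(i) rnorm(500))
  pr <- lag_correlation_profile(sequences = iid, N_max = 5)
  expect_equal(pr$r[pr$lag == 0], 1)
  expect_lt(max(abs(pr$r[pr$lag > 0])), 3 / sqrt(2000))
  # AR(1) 0.6: r(N) ~ 0.6^N
  ar <- lapply(1:4, function(i) as.numeric(arima.sim(list(ar = 0.6), 2000)))
  pr <- lag_correlation_profile(sequences = ar, N_max = 6)
  expect_lt(max(abs(pr$r[pr$lag > 0] - 0.6^(1:6))), 0.04)
})

test_that("lag correlation pairs never cross bout boundaries", {
  # poisoned sentinels: two short constant-offset bouts; cross-bout pairs
  # would produce strong positive correlation
  s1 <- rnorm(40); s2 <- rnorm(40) + 100
  pr <- lag_correlation_profile(sequences = list(s1, s2), N_max = 2)
  # independent oracle: build within-bout pairs by hand
  hand <- cor(c(s1[1:39], s2[1:39]), c(s1[2:40], s2[2:40]))
  expect_equal(pr$r[pr$lag == 1], hand, tolerance = 1e-12)
  expect_gt(hand, 0.9)  # the offset dominates pooled within-bout pairs
  # centring check: a single bout has no offset inflation
  pr1 <- lag_correlation_profile(sequences = list(s1), N_max = 2)
  expect_lt(abs(pr1$r[pr1$lag == 1]), 0.5)
})

test_that("gapped cycle indices are not treated as consecutive", {
  set.seed(32)
  x <- as.numeric(arima.sim(list(ar = 0.9), 60))
  dev <- make_dev(x, dp_y = x)
  dev$meta$cycle_idx[30:60] <- dev$meta$cycle_idx[30:60] + 5L  # gap of 5
  pr <- lag_correlation_profile(dev, leg = "L", N_max = 2)
  # oracle: pairs exactly 1 apart in cycle index
  a <- c(x[1:28], x[30:59]); b <- c(x[2:29], x[31:60])
  expect_equal(pr$r[pr$lag == 1], cor(a, b), tolerance = 1e-12)
})

test_that("exact exponential decay is fitted to machine-level accuracy", {
  lag <- 0:8
  r <- 0.8 * exp(-lag / 2)
  r[1] <- 1
  pr <- data.frame(lag = lag, r = r, n_pairs = 100)
  class(pr) <- c("lag_profile", class(pr))
  ts <- fit_decay_timescale(pr, n_boot = 0)
  expect_equal(ts$tau, 2, tolerance = 1e-6)
  expect_equal(ts$r0, 0.8, tolerance = 1e-6)
})

test_that("AR(1) timescale matches the analytic relation within the CI", {
  set.seed(33)
  ar <- lapply(1:6, function(i) as.numeric(arima.sim(list(ar = 0.6), 600)))
  pr <- lag_correlation_profile(sequences = ar, N_max = 8)
  ts <- fit_decay_timescale(pr, n_boot = 300, seed = 2)
  expect_gt(-1 / log(0.6), ts$tau_ci[1])
  expect_lt(-1 / log(0.6), ts$tau_ci[2])
  expect_equal(ts$tau, -1 / log(0.6), tolerance = 0.25)
})

test_that("non-positive lag-1 correlation flags tau = 0", {
  pr <- data.frame(lag = 0:5, r = c(1, -0.1, 0.02, -0.01, 0.005, 0),
                   n_pairs = 50)
  class(pr) <- c("lag_profile", class(pr))
  ts <- fit_decay_timescale(pr, n_boot = 0)
  expect_equal(ts$tau, 0)
  expect_equal(ts$flag, "nonpositive_r1")
})

test_that("tau and rho are linked on simulated closed-loop walkers", {
  fx <- cached("biped_small", sim_processed("biped", 2, 200, seed = 55))
  rho <- mean(vapply(unique(fx$dev$meta$animal), function(an)
    fit_return_map(fx$dev, 0.75, leg = "foot_left",
                   animal = an)$spectral_radius, numeric(1)))
  pr <- lag_correlation_profile(fx$dev, leg = "foot_right", N_max = 8)
  ts <- fit_decay_timescale(pr, n_boot = 200, seed = 3)
  expect_gt(-1 / log(rho), ts$tau_ci[1] - 0.2)
  expect_lt(-1 / log(rho), ts$tau_ci[2] + 0.2)
})

test_that("error reduction responds to feedback and rejects degenerate input", {
  # constructed positive relation
  set.seed(34)
  fx <- cached("biped_g05", sim_processed("biped", 6, 120, seed = 61,
                                          gain = 0.5))
  er <- error_reduction_analysis(fx$dev, leg = c("foot_left", "foot_right"))
  expect_gt(er$slope, 0)
  expect_lt(er$p, 0.05)
  # all-zero errors: degenerate
  dev0 <- make_dev(rep(0, 60), dp_y = rep(0, 60))
  dev0$dQ[] <- 0
  expect_error(error_reduction_analysis(dev0, leg = "L"),
               "degenerate|extendable")
  # too few contacts
  dev_small <- make_dev(rnorm(10), dp_y = rnorm(10))
  expect_error(error_reduction_analysis(dev_small, leg = "L"), "extendable")
})
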