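test_that("linear velocity model: exact line gives R2 = 1 and exact slope", {
  set.seed(10)
  v <- runif(60, 0.8, 1.6)
  cyc <- make_cycles(v, p_x = 0.2 + 0.4 * v, p_y = 0.1, duration = 1 / v)
  fit <- fit_linear_velocity_model(cyc, "length")
  expect_equal(fit$beta1, 0.4, tolerance = 1e-10)
  expect_equal(fit$r2, 1, tolerance = 1e-10)
})

test_that("constant step length across speeds gives a flat nonsignificant slope", {
  set.seed(11)
  v <- runif(80, 0.8, 1.6)
  cyc <- make_cycles(v, p_x = 0.5 + rnorm(80, sd = 0.05), p_y = 0.1,
                     duration = 1)
  fit <- fit_linear_velocity_model(cyc, "length")
  expect_lt(abs(fit$beta1), 3 * fit$se1)
  expect_gte(fit$p_slope, 0.05)
  # degenerate speeds are rejected
  cyc0 <- make_cycles(rep(1, 30), p_x = rnorm(30), p_y = 0.1, duration = 1)
  expect_error(fit_linear_velocity_model(cyc0, "length"), "degenerate")
})

test_that("simulator length slope is recovered within 3 SE", {
  fx <- cached("biped_small", sim_processed("biped", 2, 200, seed = 55))
  lf <- fx$ff$length_fits
  for (i in seq_len(nrow(lf)))
    expect_lt(abs(lf$beta1[i] - 0.4), 3 * lf$se1[i])
})

test_that("exponential duration model recovers generative parameters", {
  set.seed(12)
  v <- runif(300, 0.3, 2.5)
  beta <- c(0.5, 2.0, 1.0, 0.3)
  d <- beta[1] * exp(-beta[2] * (v - beta[3])) + beta[4] + rnorm(300, sd = 0.01)
  cyc <- make_cycles(v, p_x = 0.5, p_y = 0.1, duration = d)
  fits <- fit_exponential_duration_model(cyc)
  fit <- fits[[1]]
  expect_true(fit$converged)
  # identifiable comparison: fitted curve vs generative curve
  vv <- seq(0.4, 2.4, length.out = 25)
  truth <- beta[1] * exp(-beta[2] * (vv - beta[3])) + beta[4]
  expect_lt(max(abs(stablegait:::predict_duration(fit, vv) - truth)), 0.02)
  # decay rate is identifiable: recovered within 3 SE
  expect_lt(abs(fit$beta[2] - beta[2]), 3 * max(fit$se[2], 1e-3))
})

test_that("constant duration collapses the exponential to an offset", {
  set.seed(13)
  v <- runif(100, 0.5, 2)
  cyc <- make_cycles(v, p_x = 0.5, p_y = 0.1,
                     duration = 0.8 + rnorm(100, sd = 0.002))
  fit <- fit_exponential_duration_model(cyc)[[1]]
  pred <- stablegait:::predict_duration(fit, seq(0.6, 1.9, length.out = 10))
  expect_lt(max(abs(pred - 0.8)), 0.02)
})

test_that("fitted duration curve is nonincreasing when b0, b1 > 0", {
  set.seed(14)
  v <- runif(200, 0.5, 2)
  d <- 0.4 * exp(-1.5 * (v - 1)) + 0.3 + rnorm(200, sd = 0.01)
  fit <- fit_exponential_duration_model(make_cycles(v, 0.5, 0.1, d))[[1]]
  expect_true(fit$beta[1] > 0 && fit$beta[2] > 0)
  vv <- seq(0.5, 2, length.out = 50)
  expect_true(all(diff(stablegait:::predict_duration(fit, vv)) <= 1e-12))
})

test_that("nominal pattern with no velocity dependence equals per-phase means", {
  set.seed(15)
  n <- 60; M <- 5
  v <- runif(n, 0.8, 1.6)
  shape <- sin(seq(0, 2 * pi, length.out = M))
  Q_fun <- function(vh) cbind(body_x_pos = shape, body_y_pos = 2 * shape,
                              body_x_vel = 0.3, body_y_vel = -0.1) +
    matrix(rnorm(M * 4, sd = 1e-4), M, 4)
  cyc <- make_cycles(v, p_x = 0.5, p_y = 0.1, duration = 1, M = M,
                     Q_fun = Q_fun)
  nom <- fit_nominal_pattern(cyc)
  co <- nom[[1]]$coef_Q
  expect_lt(max(abs(co["slope", , ])), 2e-3)
  # closed form: with slope ~ 0 the nominal equals the per-phase mean
  for (m in 1:M)
    expect_equal(co["intercept", m, "body_y_pos"] +
                   co["slope", m, "body_y_pos"] * mean(v),
                 mean(cyc$Q[, m, "body_y_pos"]), tolerance = 1e-4)
})

test_that("per-phase slopes recover a linear speed-dependent excursion", {
  set.seed(16)
  n <- 100; M <- 6
  v <- runif(n, 0.8, 1.6)
  cyc <- make_cycles(v, p_x = 0.5, p_y = 0.1, duration = 1, M = M)
  slope_true <- seq(0.5, 1.5, length.out = M)
  for (i in seq_len(n))
    cyc$Q[i, , "body_y_pos"] <- slope_true * v[i] + rnorm(M, sd = 0.01)
  nom <- fit_nominal_pattern(cyc)
  expect_equal(unname(nom[[1]]$coef_Q["slope", , "body_y_pos"]), slope_true,
               tolerance = 0.05)
})

test_that("deviations have the in-sample OLS zero-mean property", {
  fx <- cached("biped_small", sim_processed("biped", 2, 200, seed = 55))
  dev <- fx$dev
  for (an in unique(dev$meta$animal)) for (lg in unique(dev$meta$leg)) {
    sel <- dev$meta$animal == an & dev$meta$leg == lg
    scale_q <- sd(dev$dQ[sel, , "pelvis_y_pos"])
    expect_lt(abs(mean(dev$dQ[sel, 10, "pelvis_y_pos"])), 1e-8 * max(scale_q, 1))
    expect_lt(abs(mean(dev$meta$dP_y[sel])), 1e-10)
    expect_lt(abs(mean(dev$meta$dP_x[sel])), 1e-10)
  }
})

test_that("a cycle equal to its nominal has zero deviations", {
  set.seed(17)
  n <- 50; M <- 5
  v <- runif(n, 0.8, 1.6)
  cyc <- make_cycles(v, p_x = 0.2 + 0.4 * v, p_y = 0.1 + 0 * v,
                     duration = 0.9 + 0.1 * exp(-v))
  for (i in seq_len(n)) {
    cyc$Q[i, , ] <- outer(rep(1, M), c(1, 2, 3, 4)) * v[i]
    cyc$Q_tilde[i, , ] <- outer(rep(1, M), c(5, 6, 7, 8)) * v[i]
  }
  ff <- fit_feedforward(cyc, min_cycles = 10)
  dev <- compute_deviations(cyc, ff)
  expect_lt(max(abs(dev$dQ)), 1e-8)
  expect_lt(max(abs(dev$dQt)), 1e-8)
  expect_lt(max(abs(dev$meta$dP_x)), 1e-8)
})

test_that("placement deviations match execution noise on simulations", {
  fx <- cached("biped_small", sim_processed("biped", 2, 200, seed = 55))
  sf <- fx$params$sigma_foot
  # dP_x carries the timing-jitter noise in step length; dP_y carries
  # execution noise plus feedback corrections: both centered on zero
  expect_equal(mean(fx$dev$meta$dP_x), 0, tolerance = 1e-10)
  expect_gt(sd(fx$dev$meta$dP_y), sf)      # feedback adds variance
})

test_that("feedforward fits are per-animal: pooling does not change them", {
  fx <- cached("biped_small", sim_processed("biped", 2, 200, seed = 55))
  one <- fx$cycles
  keep <- one$meta$animal == "ind01"
  solo <- structure(list(meta = one$meta[keep, ], Q = one$Q[keep, , ],
                         Q_tilde = one$Q_tilde[keep, , ], phase = one$phase,
                         profile = one$profile), class = "gait_cycles")
  f_solo <- fit_linear_velocity_model(solo, "length")
  f_all <- fit_linear_velocity_model(fx$cycles, "length")
  merged <- merge(f_solo, f_all, by = c("animal", "leg"))
  expect_equal(merged$beta1.x, merged$beta1.y, tolerance = 1e-12)
})

test_that("timing-width dependence is detected when constructed, absent when not", {
  fx <- cached("biped_small", sim_processed("biped", 2, 200, seed = 55))
  tw <- timing_width_independence(fx$dev, fx$ff)
  expect_true(all(c("xi", "p") %in% names(tw)))
  # power: make width deviation a deterministic function of timing deviation
  dev2 <- fx$dev
  rows <- which(dev2$meta$leg == "foot_left")[1:200]
  dev2$meta <- dev2$meta[rows, ]
  dev2$dQ <- dev2$dQ[rows, , , drop = FALSE]
  dev2$dQt <- dev2$dQt[rows, , , drop = FALSE]
  ffb <- fx$ff
  info <- ffb$by[["ind01|foot_left"]]
  # |p_y| deviation becomes quadratic in d_duration
  dev2$meta$p_y <- (info$width$beta[1] + info$width$beta[2] * dev2$meta$v_hat) +
    50 * dev2$meta$d_duration^2 + rnorm(200, sd = 1e-4)
  tw2 <- timing_width_independence(dev2, ffb)
  expect_lt(tw2$p[tw2$leg == "foot_left"], 0.05)
})

test_that("degenerate near-constant deviations do not break the xi test", {
  set.seed(18)
  x <- rep(0, 30) + rnorm(30, sd = 1e-12)
  y <- rep(0, 30) + rnorm(30, sd = 1e-12)
  r <- chatterjee_xi(x, y)
  expect_true(is.finite(r$xi))
  expect_true(r$p >= 0 && r$p <= 1)
})
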