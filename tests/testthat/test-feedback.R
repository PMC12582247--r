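test_that("exact linear deviations give exact gains and R2 = 1", {
  set.seed(20)
  dq <- rnorm(100)
  dev <- make_dev(dq, dp_y = 0.4 * dq)
  fit <- fit_error_map(dev, 0.5, "lateral")
  expect_equal(unname(fit$gains["body_y_pos"]), 0.4, tolerance = 1e-12)
  expect_equal(unname(fit$gains["intercept"]), 0, tolerance = 1e-12)
  expect_equal(fit$r2, 1, tolerance = 1e-12)
  # with an intercept and a second channel
  z <- rnorm(100)
  dev2 <- make_dev(dq, dp_y = 1.5 - 0.7 * dq + 0.2 * z,
                   extra_channels = list(body_x_pos = z))
  fit2 <- fit_error_map(dev2, 0.5, "lateral")
  expect_equal(unname(fit2$gains[c("intercept", "body_y_pos", "body_x_pos")]),
               c(1.5, -0.7, 0.2), tolerance = 1e-10)
})

test_that("baseline map hits R2 = 1 as phase approaches the contact", {
  fx <- cached("biped_small", sim_processed("biped", 2, 200, seed = 55))
  fit <- fit_baseline_map(fx$dev, 1, "lateral", animal = "ind01",
                          leg = "foot_left")
  expect_gt(fit$r2, 0.9)
  # and is weaker than the body-state model at swing onset
  sw <- median(fx$dev$meta$phi_swing)
  fb <- fit_error_map(fx$dev, sw, "lateral", animal = "ind01",
                      leg = "foot_left")
  fs <- fit_baseline_map(fx$dev, sw, "lateral", animal = "ind01",
                         leg = "foot_left")
  expect_gt(fb$r2, fs$r2)
})

test_that("independent response inflates in-sample R2 by about N/(n-1)", {
  set.seed(21)
  n <- 80; reps <- 200
  r2 <- replicate(reps, {
    dq <- rnorm(n)
    dev <- make_dev(dq, dp_y = rnorm(n),
                    extra_channels = list(body_x_pos = rnorm(n),
                                          body_y_vel = rnorm(n)))
    fit_error_map(dev, 0.5, "lateral")$r2
  })
  expect_lt(abs(mean(r2) - 3 / (n - 1)), 0.01)
})

test_that("duplicated predictors trigger the degenerate-design fallback", {
  set.seed(22)
  dq <- rnorm(60)
  dev <- make_dev(dq, dp_y = 0.3 * dq,
                  extra_channels = list(body_y_vel = dq))  # exact duplicate
  fit <- expect_silent(fit_error_map(dev, 0.5, "lateral"))
  expect_true(all(is.finite(fit$gains)))
  expect_true(fit$ridged)
  expect_equal(unname(fit$gains["body_y_pos"] + fit$gains["body_y_vel"]), 0.3,
               tolerance = 1e-4)
  # constant predictors are dropped rather than ridged
  dev2 <- make_dev(dq, dp_y = 0.3 * dq,
                   extra_channels = list(body_y_vel = rep(0, 60)))
  fit2 <- fit_error_map(dev2, 0.5, "lateral")
  expect_false(fit2$ridged)
  expect_identical(fit2$dropped, "body_y_vel")
})

test_that("scaling lateral coordinates scales the intercept and keeps R2", {
  fx <- cached("biped_small", sim_processed("biped", 2, 200, seed = 55))
  dev <- fx$dev
  s <- 2.5
  dev_s <- dev
  ylat <- grep("_y_", dimnames(dev$dQ)[[3]])
  dev_s$dQ[, , ylat] <- s * dev$dQ[, , ylat]
  dev_s$dQt[, , c(2, 4)] <- s * dev$dQt[, , c(2, 4)]
  dev_s$meta$dP_y <- s * dev$meta$dP_y
  f0 <- fit_error_map(dev, 0.6, "lateral", animal = "ind01", leg = "foot_left")
  f1 <- fit_error_map(dev_s, 0.6, "lateral", animal = "ind01",
                      leg = "foot_left")
  expect_equal(f1$r2, f0$r2, tolerance = 1e-10)
  expect_equal(unname(f1$gains["intercept"]), s * unname(f0$gains["intercept"]),
               tolerance = 1e-10)
  expect_equal(unname(f1$gains["pelvis_y_pos"]),
               unname(f0$gains["pelvis_y_pos"]), tolerance = 1e-10)
})

test_that("r2 phase profiles separate models only when feedback is present", {
  fb <- cached("biped_g05", sim_processed("biped", 6, 120, seed = 61,
                                          gain = 0.5))
  prof <- r2_phase_profile(fb$dev, "lateral",
                           leg = c("foot_left", "foot_right"))
  # body-state R2 exceeds baseline in the half-cycle before swing onset
  # (the window between the stance reference contact and liftoff, where
  # the corrective mapping the generator encodes is fully expressed)
  pre <- which(prof$phase > 0.52 & prof$phase < prof$swing_onset - 0.03)
  expect_true(mean(prof$median_body[pre] > prof$median_base[pre]) > 0.9)
  expect_true(any(prof$ks_p[pre] < 0.05))
  # identical samples give KS p = 1
  prof_id <- prof
  expect_equal(suppressWarnings(
    stats::ks.test(prof$r2_body[, 3], prof$r2_body[, 3])$p.value), 1)
})

test_that("control magnitude is zero for identical models and ordered in gain", {
  cmp <- list(r2_body = matrix(runif(20), 4), r2_base = NULL)
  cmp$r2_base <- cmp$r2_body
  class(cmp) <- "model_comparison"
  expect_equal(control_magnitude(cmp)$median, 0)

  lo <- cached("biped_g02", sim_processed("biped", 4, 120, seed = 63,
                                          gain = 0.2))
  hi <- cached("biped_g06", sim_processed("biped", 4, 120, seed = 64,
                                          gain = 0.6))
  m_lo <- control_magnitude(r2_phase_profile(lo$dev, "lateral",
                                             leg = c("foot_left", "foot_right"),
                                             min_animals = 4))
  m_hi <- control_magnitude(r2_phase_profile(hi$dev, "lateral",
                                             leg = c("foot_left", "foot_right"),
                                             min_animals = 4))
  expect_gt(m_hi$median, m_lo$median)
})

test_that("directional gains recover an asymmetric generator", {
  fx <- cached("biped_dir", sim_processed("biped", 4, 250, seed = 65,
                                          gain_lateral = 0.6,
                                          gain_medial = 0.2))
  dg <- directional_gains(fx$dev, leg = c("foot_left", "foot_right"))
  expect_gte(nrow(dg$per_animal), 3)
  expect_true(all(dg$per_animal$gain_lateral > dg$per_animal$gain_medial))
  expect_gt(dg$test$d, 0.8)
  # symmetric generator: no systematic ordering
  fs <- cached("biped_small", sim_processed("biped", 2, 200, seed = 55))
  dgs <- directional_gains(fs$dev, leg = c("foot_left", "foot_right"))
  diffs <- dgs$per_animal$gain_lateral - dgs$per_animal$gain_medial
  expect_lt(abs(mean(diffs)), 0.15)
})

test_that("one-signed errors exercise the exclusion path", {
  set.seed(23)
  dq <- abs(rnorm(120)) + 0.1   # all positive, ref_side = 1: all medial
  dev <- make_dev(dq, dp_y = 0.4 * dq)
  dg <- directional_gains(dev, phi = 0.5, leg = "L", min_n = 10)
  expect_null(dg$per_animal)
  expect_identical(dg$excluded, "a1")
})

test_that("shuffling placements destroys the body-state advantage", {
  fx <- cached("biped_small", sim_processed("biped", 2, 200, seed = 55))
  dev <- fx$dev
  set.seed(24)
  dev$meta$dP_y <- sample(dev$meta$dP_y)
  sw <- median(dev$meta$phi_swing)
  fit <- fit_error_map(dev, sw, "lateral", animal = "ind01",
                       leg = c("foot_left", "foot_right"))
  n <- fit$n; N <- dim(dev$dQ)[3]
  # in-sample R2 falls to the null inflation level
  expect_lt(fit$r2, N / (n - 1) + 3 * sqrt(2 * N) / n)
})
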