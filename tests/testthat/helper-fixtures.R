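`%||%` <- function(a, b) if (is.null(a)) b else a

# shared fixture cache: expensive simulations are built once per test run
.sg_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .sg_cache)) {
    assign(name, force(expr), envir = .sg_cache)
  }
  get(name, envir = .sg_cache)
}

# simulate n_ind individuals, process them, fit the feedforward module and
# compute deviations; returns everything downstream tests need
sim_processed <- function(species, n_ind, n_cycles, seed, ...) {
  set.seed(seed)
  sims <- list()
  per <- lapply(seq_len(n_ind), function(i) {
    p <- walker_params(species, ...)
    sim <- simulate_walker(p, n_cycles = n_cycles,
                           bout_id = sprintf("b%02d", i))
    sims[[i]] <<- sim
    b <- align_heading(select_straight_bouts(list(sim$bout))[[1]])
    build_cycles(list(b), p$profile, animal = sprintf("ind%02d", i))
  })
  cyc <- combine_cycles(per)
  ff <- fit_feedforward(cyc)
  dev <- compute_deviations(cyc, ff)
  list(sims = sims, cycles = cyc, ff = ff, dev = dev,
       profile = sims[[1]]$params$profile,
       params = sims[[1]]$params)
}

front_legs <- function(profile) {
  lv <- sub("_(left|right)$", "", profile$leg_labels)
  profile$leg_labels[lv == lv[1]]
}

mean_gain_at <- function(dev, phi, legs) {
  vapply(unique(dev$meta$animal), function(an) {
    fit <- fit_error_map(dev, phi, "lateral", animal = an, leg = legs)
    sum(fit$gains[grep("_y_pos$", names(fit$gains))])
  }, numeric(1))
}

# per-animal summed lateral gain with its standard error
gain_fits_at <- function(dev, phi, legs) {
  do.call(rbind, lapply(unique(dev$meta$animal), function(an) {
    fit <- fit_error_map(dev, phi, "lateral", animal = an, leg = legs)
    data.frame(animal = an,
               gain = sum(fit$gains[grep("_y_pos$", names(fit$gains))]),
               se = stablegait:::lateral_gain_se(fit))
  }))
}

# hand-built deviation_set with a single body channel, for exact-oracle
# tests: dQ constant across phase, dP as supplied
make_dev <- function(dq, dp_y, dp_x = NULL, animal = "a1", leg = "L",
                     M = 5L, bout = "b1", ref_side = 1,
                     dqt = NULL, extra_channels = NULL) {
  n <- length(dp_y)
  meta <- data.frame(animal = animal, bout = bout, leg = leg,
                     cycle_idx = seq_len(n), t0 = seq_len(n), t1 = seq_len(n) + 1,
                     duration = 1, v_hat = 1, phi_swing = 0.6,
                     p_x = 0, p_y = 0, ref_leg = "R", ref_side = ref_side,
                     dP_x = dp_x %||% rep(0, n), dP_y = dp_y,
                     d_duration = 0, extrapolated = FALSE,
                     stringsAsFactors = FALSE)
  chans <- c(list(body_y_pos = dq), extra_channels)
  dQ <- array(NA_real_, c(n, M, length(chans)),
              dimnames = list(NULL, NULL, names(chans)))
  for (j in seq_along(chans)) dQ[, , j] <- matrix(chans[[j]], n, M)
  dQt <- array(if (is.null(dqt)) stats::rnorm(n * M * 4) else dqt,
               c(n, M, 4L),
               dimnames = list(NULL, NULL, c("foot_x_pos", "foot_y_pos",
                                             "foot_x_vel", "foot_y_vel")))
  structure(list(meta = meta, dQ = dQ, dQt = dQt,
                 phase = seq(0, 1, length.out = M),
                 profile = profile_biped()),
            class = "deviation_set")
}

# hand-built gait_cycles with given v_hat / placement / duration columns
make_cycles <- function(v_hat, p_x, p_y, duration, animal = "a1", leg = "L",
                        M = 5L, Q_fun = NULL) {
  n <- length(v_hat)
  meta <- data.frame(animal = animal, bout = "b1", leg = leg,
                     cycle_idx = seq_len(n), t0 = seq_len(n),
                     t1 = seq_len(n) + duration, duration = duration,
                     v_hat = v_hat, phi_swing = 0.6, p_x = p_x, p_y = p_y,
                     ref_leg = "R", ref_side = 1, stringsAsFactors = FALSE)
  Q <- array(stats::rnorm(n * M * 4, sd = 1e-6), c(n, M, 4),
             dimnames = list(NULL, NULL, c("body_x_pos", "body_y_pos",
                                           "body_x_vel", "body_y_vel")))
  if (!is.null(Q_fun)) for (i in seq_len(n)) Q[i, , ] <- Q_fun(v_hat[i])
  Qt <- array(stats::rnorm(n * M * 4, sd = 1e-6), c(n, M, 4),
              dimnames = list(NULL, NULL, c("foot_x_pos", "foot_y_pos",
                                            "foot_x_vel", "foot_y_vel")))
  structure(list(meta = meta, Q = Q, Q_tilde = Qt,
                 phase = seq(0, 1, length.out = M), profile = profile_biped()),
            class = "gait_cycles")
}
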