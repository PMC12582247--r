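#' Parameters of the stochastic legged walker
#'
#' The walker is a kinematic generative model of the hypothesized
#' feedforward-feedback control structure, not a mechanical simulator. A
#' feedforward layer turns a per-cycle commanded speed into nominal step
#' geometry and timing; a feedback layer maps the lateral body-state error
#' onto a corrective component of the next foot placement.
#'
#' Step geometry and cycle timing are kinematically linked in a world-frame
#' walker with two alternating support groups: the same-leg stride must
#' equal the body advance over one cycle, so `2 * L(v) = v * T(v)`. The
#' generator therefore takes one law as primary. With
#' `timing = "from_length"` (default) the linear step-length law
#' `L(v) = length_beta[1] + length_beta[2] * v` is commanded and the cycle
#' duration is derived as `T(v) = 2 L(v) / v`; with
#' `timing = "from_duration"` the exponential duration law
#' `T(v) = duration_beta[1] * exp(-duration_beta[2] * (v - duration_beta[3]))
#' + duration_beta[4]` is commanded and step length is derived.
#'
#' The lateral error dynamics are step-discrete. With per-cycle body error
#' `e_n`, feedback gain `G`, persistence `a` and unit coupling of the
#' commanded correction, `dP_n = G e_n + eps` and
#' `e_(n+1) = a e_n - G e_n + eta`, so the closed-loop cycle-to-cycle
#' coefficient is `lambda = a - G`: placement deviations decorrelate as
#' `lambda^N` and the cycle return map has spectral radius `|lambda|`.
#' The execution scatter `eps` perturbs where the foot lands but not the
#' body dynamics.
#'
#' @param profile A `species_profile` (or one of the built-in profile
#'   names: `"biped"`, `"quadruped"`, `"hexapod"`, which also select
#'   species-appropriate defaults for all other parameters).
#' @param v_mean,v_sd Commanded speed distribution (length/s); the
#'   per-cycle speed follows a stationary AR(1) with this mean and
#'   marginal SD, truncated positive.
#' @param v_persistence Cycle-to-cycle autocorrelation of the commanded
#'   speed, in [0, 1) (default 0.5): natural locomotor speed varies
#'   smoothly within a bout rather than jumping independently each cycle.
#' @param length_beta `c(b0, b1)`: linear step length law (length units).
#' @param width_beta `c(b0, b1)`: linear step width law.
#' @param duration_beta `c(b0, b1, b2, b3)`: exponential duration law,
#'   used when `timing = "from_duration"`.
#' @param timing `"from_length"` or `"from_duration"` (see Details).
#' @param duty Stance fraction of the cycle, in (0, 1).
#' @param a Step-to-step persistence of the lateral body error, |a| < 1.
#' @param gain Lateral feedback gain G: fraction of the body error mapped
#'   into the next placement.
#' @param gain_medial,gain_lateral Optional direction-specific gains used
#'   in place of `gain` for errors directed toward / away from the current
#'   stance reference foot; default both equal `gain`.
#' @param gain_by_leg Optional named multiplier of the gain per leg.
#' @param sigma_body Per-cycle lateral body-state noise SD.
#' @param sigma_foot Placement execution noise SD (independent per leg).
#' @param sigma_obs Per-frame marker observation noise SD.
#' @param sigma_duration Multiplicative per-cycle timing jitter SD.
#' @param ramp_frac Fraction of each half-cycle window over which the
#'   rendered body error eases to its new value.
#' @param body_marker_offsets Named numeric fore-aft offsets of the body
#'   markers relative to the body reference point.
#' @param curvature Heading drift in degrees per second (0 = straight);
#'   nonzero values exist to exercise straightness selection.
#' @param seed Optional RNG seed stored with the parameters.
#' @return An object of class `walker_params`.
#' @export
walker_params <- function(profile = "biped",
                          v_mean = NULL, v_sd = NULL, v_persistence = 0.5,
                          length_beta = NULL, width_beta = NULL,
                          duration_beta = NULL,
                          timing = c("from_length", "from_duration"),
                          duty = 0.62, a = 0.9, gain = 0.4,
                          gain_medial = NULL, gain_lateral = NULL,
                          gain_by_leg = NULL,
                          sigma_body = NULL, sigma_foot = NULL,
                          sigma_obs = NULL, sigma_duration = 0.02,
                          ramp_frac = 0.08,
                          body_marker_offsets = NULL,
                          curvature = 0, seed = NULL) {
  timing <- match.arg(timing)
  if (is.character(profile)) {
    profile <- switch(profile,
                      biped = profile_biped(),
                      quadruped = profile_quadruped(),
                      hexapod = profile_hexapod(),
                      stop("unknown built-in profile: ", profile))
  }
  def <- switch(profile$name,
    biped = list(v_mean = 1.2, v_sd = 0.15, length_beta = c(0.2, 0.4),
                 width_beta = c(0.12, 0), sigma_body = 0.012,
                 sigma_foot = 0.003, sigma_obs = 0.002,
                 offsets = c(pelvis = 0)),
    quadruped = list(v_mean = 100, v_sd = 15, length_beta = c(10, 0.3),
                     width_beta = c(25, 0), sigma_body = 1.2,
                     sigma_foot = 0.3, sigma_obs = 0.25,
                     offsets = c(nose = 30, tail_base = -30)),
    hexapod = list(v_mean = 20, v_sd = 3.5, length_beta = c(1, 0.08),
                   width_beta = c(2.5, 0), sigma_body = 0.12,
                   sigma_foot = 0.03, sigma_obs = 0.02,
                   offsets = c(head = 2)),
    list(v_mean = 1, v_sd = 0.15, length_beta = c(0.2, 0.4),
         width_beta = c(0.2, 0), sigma_body = 0.02, sigma_foot = 0.01,
         sigma_obs = 0.003,
         offsets = stats::setNames(rep(0, length(profile$body_markers)),
                                   profile$body_markers)))
  p <- list(
    profile = profile,
    v_mean = v_mean %||% def$v_mean, v_sd = v_sd %||% def$v_sd,
    v_persistence = v_persistence,
    length_beta = length_beta %||% def$length_beta,
    width_beta = width_beta %||% def$width_beta,
    duration_beta = duration_beta,
    timing = timing, duty = duty, a = a, c = 1,
    gain = gain,
    gain_medial = gain_medial %||% gain,
    gain_lateral = gain_lateral %||% gain,
    gain_by_leg = gain_by_leg,
    sigma_body = sigma_body %||% def$sigma_body,
    sigma_foot = sigma_foot %||% def$sigma_foot,
    sigma_obs = sigma_obs %||% def$sigma_obs,
    sigma_duration = sigma_duration, ramp_frac = ramp_frac,
    body_marker_offsets = body_marker_offsets %||% def$offsets,
    curvature = curvature, seed = seed
  )
  if (abs(p$a) >= 1) stop("|a| must be < 1")
  if (p$v_persistence < 0 || p$v_persistence >= 1)
    stop("v_persistence must be in [0, 1)")
  if (p$duty <= 0 || p$duty >= 1) stop("duty must be in (0, 1)")
  for (s in c("sigma_body", "sigma_foot", "sigma_obs", "sigma_duration"))
    if (p[[s]] < 0) stop(s, " must be >= 0")
  if (p$timing == "from_duration") {
    if (is.null(p$duration_beta) || length(p$duration_beta) != 4L)
      stop("timing = 'from_duration' needs duration_beta = c(b0, b1, b2, b3)")
    vr <- pmax(p$v_mean + c(-3, 0, 3) * p$v_sd, 1e-3)
    if (any(exp_duration(vr, p$duration_beta) <= 0))
      stop("duration law not positive over the commanded speed range")
  }
  vchk <- pmax(p$v_mean + c(-3, 3) * p$v_sd, 1e-3)
  if (any(p$length_beta[1] + p$length_beta[2] * vchk <= 0))
    stop("step length law not positive over the commanded speed range")
  structure(p, class = "walker_params")
}

exp_duration <- function(v, beta) {
  beta[1] * exp(-beta[2] * (v - beta[3])) + beta[4]
}

#' One step of the lateral error-correction dynamics
#'
#' Pure function for a single step of the closed loop: the feedback module
#' maps the current lateral body-state error into a placement deviation,
#' and the body error is carried to the next step with persistence `a`,
#' reduced by the placement correction (unit coupling), plus noise.
#'
#' @param state_error Current lateral body-state error.
#' @param params A `walker_params` (only `a`, `gain` and the unit coupling
#'   are used).
#' @param noise_draws Numeric pair `c(body, foot)` of noise realizations
#'   (defaults to zero: deterministic map).
#' @return List with `placement_deviation` and `next_state_error`.
#' @export
step_dynamics <- function(state_error, params, noise_draws = c(0, 0)) {
  dp <- params$gain * state_error + noise_draws[2]
  list(placement_deviation = dp,
       next_state_error = params$a * state_error - params$c * dp + noise_draws[1])
}

# step length / width / duration laws at speed v
ff_laws <- function(params, v) {
  if (params$timing == "from_length") {
    L <- params$length_beta[1] + params$length_beta[2] * v
    T <- 2 * L / v
  } else {
    T <- exp_duration(v, params$duration_beta)
    L <- v * T / 2
  }
  list(L = L, W = params$width_beta[1] + params$width_beta[2] * v, T = T)
}

#' Simulate a bout of the stochastic walker
#'
#' Draws a commanded speed per gait cycle, derives the nominal step
#' geometry and timing from the feedforward laws, iterates the lateral
#' error-correction dynamics once per cycle, schedules the two support
#' groups in antiphase, and renders continuous marker trajectories with
#' [render_trajectories()]. Ground truth (contact schedule, per-cycle body
#' errors, per-placement deviations) is returned alongside the bout.
#'
#' @param params A `walker_params`.
#' @param duration Requested bout duration in seconds (must cover at least
#'   3 gait cycles); alternatively give `n_cycles`.
#' @param n_cycles Number of gait cycles to simulate (overrides
#'   `duration`).
#' @param bout_id Label for the generated bout.
#' @param seed RNG seed; defaults to `params$seed`. Identical seeds give
#'   bit-identical results.
#' @return A list of class `simulation_result` with elements `bout`
#'   (a `trajectory_bout`), `truth_contacts` (data frame: leg, event time,
#'   onset/offset frame, placement), `truth_states` (per-cycle lateral
#'   body errors), `truth_placement_dev` (data frame of lateral placement
#'   deviations per leg and cycle) and `params`.
#' @export
simulate_walker <- function(params, duration = NULL, n_cycles = NULL,
                            bout_id = "sim", seed = NULL) {
  seed <- seed %||% params$seed
  if (!is.null(seed)) set.seed(seed)
  pr <- params$profile
  if (is.null(n_cycles)) {
    if (is.null(duration)) stop("give duration or n_cycles")
    t_nom <- ff_laws(params, params$v_mean)$T
    n_cycles <- floor(duration / t_nom)
    if (n_cycles < 3) stop("duration must cover at least 3 gait cycles")
  }
  if (n_cycles < 3) stop("need at least 3 gait cycles")
  N <- as.integer(n_cycles)

  # --- per-cycle feedforward draws -------------------------------------
  # stationary AR(1) speed with the commanded marginal distribution
  rho_v <- params$v_persistence
  z <- stats::rnorm(N)
  v <- numeric(N)
  v[1] <- params$v_mean + params$v_sd * z[1]
  for (n in seq_len(N - 1L))
    v[n + 1L] <- params$v_mean + rho_v * (v[n] - params$v_mean) +
      params$v_sd * sqrt(1 - rho_v^2) * z[n + 1L]
  v <- pmax(v, 0.05 * params$v_mean)
  laws <- ff_laws(params, v)
  Tn <- laws$T * (1 + params$sigma_duration * stats::rnorm(N))
  Tn <- pmax(Tn, 0.2 * laws$T)
  t_end <- cumsum(Tn)                      # group-1 contact events
  t_mid <- t_end - Tn / 2                  # group-2 contact events
  cyc_start <- c(0, t_end[-N])

  g1 <- pr$limb_groups[[1]]; g2 <- pr$limb_groups[[2]]
  ref1 <- g1[order(match(g1, pr$leg_labels))][1L]   # front limb, group 1
  ref2 <- g2[order(match(g2, pr$leg_labels))][1L]   # front limb, group 2
  side <- vapply(pr$leg_labels, leg_side, numeric(1), profile = pr)
  mult <- rep(1, pr$n_legs); names(mult) <- pr$leg_labels
  if (!is.null(params$gain_by_leg))
    mult[names(params$gain_by_leg)] <- params$gain_by_leg

  lam <- params$a - params$gain
  sd_stat <- params$sigma_body / sqrt(max(1 - lam^2, 0.05))
  delta0 <- stats::rnorm(1, 0, sd_stat)
  eta <- stats::rnorm(N, 0, params$sigma_body)
  eps0 <- stats::rnorm(pr$n_legs, 0, params$sigma_foot)
  names(eps0) <- pr$leg_labels
  eps <- matrix(stats::rnorm(N * pr$n_legs, 0, params$sigma_foot),
                N, pr$n_legs, dimnames = list(NULL, pr$leg_labels))

  # event-level bookkeeping: per cycle, group 2 places at t_mid with the
  # cycle's error, group 1 at t_end; the error updates after the group-1
  # event with unit coupling to the commanded correction (execution
  # scatter eps lands in the foot position but is end-effector noise,
  # independent of the body dynamics; body-level noise is eta).
  delta <- numeric(N)
  dev <- matrix(NA_real_, N, pr$n_legs, dimnames = list(NULL, pr$leg_labels))
  d <- delta0
  # directional gain relative to the stance anchor active at each event
  dir_gain <- function(err, anchor_side) {
    if (err * anchor_side > 0) params$gain_medial else params$gain_lateral
  }
  for (n in seq_len(N)) {
    delta[n] <- d
    for (leg in g2)            # anchored to group-1 front limb
      dev[n, leg] <- dir_gain(d, side[ref1]) * mult[leg] * d + eps[n, leg]
    for (leg in g1)            # anchored to group-2 front limb
      dev[n, leg] <- dir_gain(d, side[ref2]) * mult[leg] * d + eps[n, leg]
    d <- params$a * d - params$c * (dev[n, ref1] - eps[n, ref1]) + eta[n]
  }

  # --- world-frame placement lattice -----------------------------------
  # body x integrates the commanded speed; feet land ahead of the body by
  # duty * L so the signed foot-minus-body displacement is symmetric
  cumx <- c(0, cumsum(v * Tn))
  x_at <- function(tt) {
    n <- pmin(pmax(findInterval(tt, c(0, t_end)), 1L), N)
    cumx[n] + v[n] * (tt - cyc_start[n])
  }
  half_w <- function(leg, n) side[leg] * laws$W[n] / 2
  # landing lead: feet touch down ahead of the body by a fixed fraction of
  # the nominal step length at the mean commanded speed. A per-cycle lead
  # would leak the step-length law's cycle-to-cycle jumps into the
  # opposite-group-referenced step length measure.
  L_bar <- ff_laws(params, params$v_mean)$L
  lead <- params$duty * L_bar

  legs <- pr$leg_labels
  # one contact event per leg per cycle, plus one pre-bout row (row 1):
  # group 1 places at t = 0 (event 0), group 2 has a virtual stance begun
  # half a cycle before the bout starts
  E <- N + 1L
  ev_time <- ev_x <- ev_y <- ev_dev <- matrix(NA_real_, E, pr$n_legs,
                                              dimnames = list(NULL, pr$leg_labels))
  ev_cycle <- matrix(rep(0:N, pr$n_legs), E, pr$n_legs,
                     dimnames = list(NULL, pr$leg_labels))
  for (leg in g2) {
    ev_time[1, leg] <- -Tn[1] / 2
    ev_x[1, leg] <- -v[1] * Tn[1] / 2 + lead
    ev_y[1, leg] <- half_w(leg, 1L)
    ev_dev[1, leg] <- 0
    ev_time[1L + seq_len(N), leg] <- t_mid
    ev_x[1L + seq_len(N), leg] <- x_at(t_mid) + lead
    ev_dev[1L + seq_len(N), leg] <- dev[, leg]
  }
  for (leg in g1) {
    ev_time[1, leg] <- 0
    ev_x[1, leg] <- lead
    ev_dev[1, leg] <- dir_gain(delta0, side[ref2]) * mult[leg] * delta0 + eps0[leg]
    ev_y[1, leg] <- ev_y[1, ref2] + (half_w(leg, 1L) - half_w(ref2, 1L)) +
      ev_dev[1, leg]
    ev_time[1L + seq_len(N), leg] <- t_end
    ev_x[1L + seq_len(N), leg] <- x_at(t_end) + lead
    ev_dev[1L + seq_len(N), leg] <- dev[, leg]
  }
  # lateral chaining: each placement is anchored to the latest contact of
  # the opposite group's front limb
  for (n in seq_len(N)) {
    r <- n + 1L
    for (leg in g2)
      ev_y[r, leg] <- ev_y[n, ref1] + (half_w(leg, n) - half_w(ref1, n)) +
        dev[n, leg]
    for (leg in g1)
      ev_y[r, leg] <- ev_y[r, ref2] + (half_w(leg, n) - half_w(ref2, n)) +
        dev[n, leg]
  }
  ev <- lapply(legs, function(leg)
    data.frame(time = ev_time[, leg], cycle = ev_cycle[, leg],
               x = ev_x[, leg], y = ev_y[, leg], dev_y = ev_dev[, leg]))
  names(ev) <- legs

  # body lateral target per half-cycle window: the anchor's world y, offset
  # to the body midline, plus the cycle's body error.
  # window 2n-1 = (end_{n-1}, mid_n]: anchor = group-1 front limb (placed
  # at the previous group-1 event, row n); window 2n = (mid_n, end_n]:
  # anchor = group-2 front limb (placed at mid_n, row n+1).
  win_t <- c(0, as.vector(rbind(t_mid, t_end)))     # window boundaries
  ns <- seq_len(N)
  anchor_y <- numeric(2 * N); anchor_off <- numeric(2 * N)
  anchor_y[2 * ns - 1] <- ev_y[ns, ref1]
  anchor_off[2 * ns - 1] <- half_w(ref1, ns)
  anchor_y[2 * ns] <- ev_y[ns + 1L, ref2]
  anchor_off[2 * ns] <- half_w(ref2, ns)
  Vwin <- anchor_y - anchor_off + rep(delta, each = 2)

  plan <- list(profile = pr, duty = params$duty, ramp_frac = params$ramp_frac,
               t_total = t_end[N], leg_events = ev,
               body_x = list(t_end = t_end, cyc_start = cyc_start, v = v, Tn = Tn),
               body_y = list(win_t = win_t, V = Vwin),
               body_marker_offsets = params$body_marker_offsets,
               curvature = params$curvature)
  bout <- render_trajectories(plan, params, bout_id = bout_id)

  fps <- pr$frame_rate
  tc <- do.call(rbind, lapply(legs, function(leg) {
    e <- ev[[leg]]
    e <- e[e$time >= 0, , drop = FALSE]
    gaps <- diff(e$time)
    stance <- params$duty * c(gaps, stats::median(gaps))
    data.frame(leg = leg, time = e$time, cycle = e$cycle,
               onset_index = as.integer(ceiling(e$time * fps - 1e-9)) + 1L,
               offset_index = pmin(as.integer(floor((e$time + stance) * fps + 1e-9)) + 1L,
                                   length(bout$t)),
               x = e$x, y = e$y, dev_y = e$dev_y, stringsAsFactors = FALSE)
  }))
  tpd <- tc[, c("leg", "cycle", "time", "dev_y")]
  structure(list(bout = bout, truth_contacts = tc, truth_states = delta,
                 truth_placement_dev = tpd, cycle_speeds = v,
                 cycle_durations = Tn, params = params),
            class = "simulation_result")
}

#' Render continuous marker trajectories from a discrete gait plan
#'
#' Feet are constant at their placement during stance and follow a cosine
#' ease to the next placement during swing; the body fore-aft position
#' integrates the commanded per-cycle speed; the body lateral position
#' eases (cosine, over `ramp_frac` of each half-cycle window) between the
#' per-window target values that encode the lateral body error. Per-frame
#' observation noise `sigma_obs` is added to every marker coordinate.
#'
#' @param plan Discrete plan as built by [simulate_walker()]: leg contact
#'   events, body fore-aft speed schedule, lateral window targets.
#' @param params A `walker_params`.
#' @param bout_id Label for the rendered bout.
#' @return A `trajectory_bout`.
#' @export
render_trajectories <- function(plan, params, bout_id = "sim") {
  pr <- plan$profile
  fps <- pr$frame_rate
  t <- seq(0, plan$t_total, by = 1 / fps)
  nfr <- length(t)

  # body fore-aft
  bx <- plan$body_x
  N <- length(bx$t_end)
  cumx <- c(0, cumsum(bx$v * bx$Tn))
  n_of_t <- pmin(pmax(findInterval(t, c(0, bx$t_end), rightmost.closed = TRUE), 1L), N)
  body_x <- cumx[n_of_t] + bx$v[n_of_t] * (t - bx$cyc_start[n_of_t])

  # body lateral: ease between window targets
  by <- plan$body_y
  w <- pmin(pmax(findInterval(t, by$win_t, rightmost.closed = TRUE), 1L),
            length(by$V))
  V <- by$V
  Vprev <- c(V[1], V[-length(V)])
  w_start <- by$win_t[w]
  w_len <- by$win_t[w + 1L] - w_start
  u <- (t - w_start) / (plan$ramp_frac * w_len)
  ease <- (1 - cos(pi * pmin(u, 1))) / 2
  body_y <- Vprev[w] + (V[w] - Vprev[w]) * ease

  positions <- list()
  for (m in pr$body_markers) {
    off <- plan$body_marker_offsets[[m]] %||% 0
    positions[[m]] <- cbind(x = body_x + off, y = body_y)
  }

  for (leg in pr$leg_labels) {
    e <- plan$leg_events[[leg]]
    if (any(diff(e$time) <= 0)) stop("leg ", leg, ": contact events not ordered")
    gaps <- diff(e$time)
    stance_len <- plan$duty * c(gaps, stats::median(gaps))
    se <- e$time + stance_len
    if (nrow(e) > 1L && any(se[-nrow(e)] > e$time[-1L] + 1e-9))
      stop("leg ", leg, ": overlapping stance intervals")
    i <- findInterval(t, e$time)
    i <- pmin(pmax(i, 1L), nrow(e))
    in_swing <- t > se[i] & i < nrow(e)
    fx <- e$x[i]; fy <- e$y[i]
    if (any(in_swing)) {
      j <- which(in_swing)
      ii <- i[j]
      uu <- (t[j] - se[ii]) / (e$time[ii + 1L] - se[ii])
      es <- (1 - cos(pi * pmin(pmax(uu, 0), 1))) / 2
      fx[j] <- e$x[ii] + (e$x[ii + 1L] - e$x[ii]) * es
      fy[j] <- e$y[ii] + (e$y[ii + 1L] - e$y[ii]) * es
    }
    positions[[leg]] <- cbind(x = fx, y = fy)
  }

  if (!is.null(plan$curvature) && plan$curvature != 0) {
    # curved variant: rotate body-frame offsets along a turning base path
    th <- plan$curvature * pi / 180 * t
    dt <- c(diff(t), 1 / fps)
    vx <- c(diff(body_x) / diff(t), 0)
    base_x <- cumsum(vx * cos(th) * dt)
    base_y <- cumsum(vx * sin(th) * dt)
    for (m in names(positions)) {
      relx <- positions[[m]][, "x"] - body_x
      rely <- positions[[m]][, "y"]
      positions[[m]] <- cbind(x = base_x + relx * cos(th) - rely * sin(th),
                              y = base_y + relx * sin(th) + rely * cos(th))
    }
  }

  if (params$sigma_obs > 0) {
    for (m in names(positions))
      positions[[m]] <- positions[[m]] +
        matrix(stats::rnorm(2 * nfr, 0, params$sigma_obs), nfr, 2)
  }
  trajectory_bout(bout_id, pr, t, positions, validate = FALSE)
}

#' @export
print.simulation_result <- function(x, ...) {
  cat("<simulation_result>", x$bout$bout_id, ":",
      length(x$truth_states), "cycles,",
      length(x$bout$t), "frames (", x$params$profile$name, ")\n")
  invisible(x)
}
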