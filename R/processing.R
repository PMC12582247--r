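#' Select straight-line locomotion segments
#'
#' Heading is the direction of the smoothed instantaneous planar velocity
#' of the body (mean of the profile's body markers). Maximal contiguous
#' segments whose heading range stays within the profile's straightness
#' threshold are returned as sub-bouts; segments shorter than
#' `min_cycles` nominal gait cycles are dropped.
#'
#' @param bouts List of `trajectory_bout`s.
#' @param threshold Heading range threshold in degrees (default: the
#'   profile's `straightness_threshold`).
#' @param smooth_s Moving-average window (seconds) applied to the velocity
#'   before computing heading (default 0.25).
#' @param min_cycles Minimum segment length in nominal cycles (default 3).
#' @param log Optional drop log.
#' @return List of straight `trajectory_bout`s (possibly split).
#' @export
select_straight_bouts <- function(bouts, threshold = NULL, smooth_s = 0.25,
                                  min_cycles = 3, log = NULL) {
  out <- list()
  for (bout in bouts) {
    pr <- bout$species
    thr <- threshold %||% pr$straightness_threshold
    bx <- rowMeans(sapply(pr$body_markers, function(m) bout$positions[[m]][, "x"]))
    by <- rowMeans(sapply(pr$body_markers, function(m) bout$positions[[m]][, "y"]))
    w <- max(3L, round(smooth_s * pr$frame_rate))
    vx <- moving_average(central_diff(bx, bout$t), w)
    vy <- moving_average(central_diff(by, bout$t), w)
    heading <- unwrap_angle(atan2(vy, vx)) * 180 / pi
    t_cyc <- estimate_cycle_duration(bout)
    min_len <- min_cycles * t_cyc
    segs <- straight_segments(heading, thr)
    k <- 0L
    for (s in segs) {
      if (bout$t[s[2]] - bout$t[s[1]] < min_len) {
        log_drop(log, "segment_too_short",
                 sprintf("bout %s frames %d-%d", bout$bout_id, s[1], s[2]))
        next
      }
      k <- k + 1L
      id <- if (length(segs) == 1L && s[1] == 1L && s[2] == length(bout$t))
        bout$bout_id else paste0(bout$bout_id, "_s", k)
      out[[length(out) + 1L]] <- slice_bout(bout, s[1], s[2], id)
    }
  }
  out
}

unwrap_angle <- function(theta) {
  d <- diff(theta)
  d <- d - 2 * pi * round(d / (2 * pi))
  cumsum(c(theta[1], d))
}

# maximal contiguous index ranges with max-min <= thr (greedy restart at
# the breaking sample, which excises turns as short rejected fragments)
straight_segments <- function(h, thr) {
  n <- length(h)
  segs <- list()
  start <- 1L; lo <- h[1]; hi <- h[1]
  for (i in 2:n) {
    lo2 <- min(lo, h[i]); hi2 <- max(hi, h[i])
    if (hi2 - lo2 > thr) {
      if (i - 1L > start) segs[[length(segs) + 1L]] <- c(start, i - 1L)
      start <- i; lo <- h[i]; hi <- h[i]
    } else {
      lo <- lo2; hi <- hi2
    }
  }
  if (n > start) segs[[length(segs) + 1L]] <- c(start, n)
  segs
}

# rough nominal cycle duration from the oscillation of the first foot's
# fore-aft displacement relative to the body (zero-crossing count)
estimate_cycle_duration <- function(bout) {
  pr <- bout$species
  s <- bout$positions[[pr$leg_labels[1]]][, "x"] -
    rowMeans(sapply(pr$body_markers, function(m) bout$positions[[m]][, "x"]))
  s <- moving_average(s - mean(s), max(3L, round(0.02 * length(s))))
  crossings <- sum(diff(sign(s + 1e-12)) != 0)
  dur <- diff(range(bout$t))
  if (crossings >= 2) 2 * dur / crossings else dur / 3
}

slice_bout <- function(bout, i1, i2, id = bout$bout_id) {
  trajectory_bout(id, bout$species, bout$t[i1:i2],
                  lapply(bout$positions, function(p) p[i1:i2, , drop = FALSE]),
                  validate = FALSE)
}

#' Rotate a bout so mean heading is the +x axis
#'
#' Applies one rigid planar rotation (about the origin) to every marker so
#' that the bout's net body displacement points along +x. Inter-marker
#' distances are preserved.
#'
#' @param bout A straight `trajectory_bout`.
#' @return The rotated bout.
#' @export
align_heading <- function(bout) {
  pr <- bout$species
  bx <- rowMeans(sapply(pr$body_markers, function(m) bout$positions[[m]][, "x"]))
  by <- rowMeans(sapply(pr$body_markers, function(m) bout$positions[[m]][, "y"]))
  dx <- bx[length(bx)] - bx[1]; dy <- by[length(by)] - by[1]
  if (dx^2 + dy^2 < 1e-20) stop("bout ", bout$bout_id, ": zero net displacement")
  th <- atan2(dy, dx)
  R <- matrix(c(cos(-th), sin(-th), -sin(-th), cos(-th)), 2, 2)
  bout$positions <- lapply(bout$positions, function(p) {
    q <- p %*% t(R)
    colnames(q) <- c("x", "y")
    q
  })
  bout
}

#' Detect foot contact events
#'
#' Two detectors are available. `"extrema"`: the signed fore-aft
#' displacement of the foot relative to the body is low-pass filtered;
#' stance onsets (touchdown) are its local maxima and stance ends
#' (liftoff) its local minima, subject to a minimum peak prominence (10%
#' of the displacement range) and a minimum spacing of half the running
#' median cycle duration. The signed convention makes touchdown a maximum
#' and liftoff a minimum; an unsigned distance would make both extrema of
#' the same kind. `"velocity_threshold"`: stance is where the foot's
#' planar speed stays below a fraction of the median body speed for a
#' minimum dwell. `"provided"` uses contacts stored on the bout.
#'
#' @param bout An aligned `trajectory_bout`.
#' @param leg Leg label.
#' @param method `"extrema"` (default), `"velocity_threshold"` or
#'   `"provided"`.
#' @param smooth_frames Low-pass moving-average window in frames
#'   (default 5).
#' @param prominence_frac Peak prominence as a fraction of the
#'   displacement range (default 0.1).
#' @param speed_frac Speed threshold as a fraction of median body speed
#'   (velocity method, default 0.3).
#' @param min_dwell_frac Minimum stance dwell as a fraction of the median
#'   cycle (velocity method, default 0.1).
#' @return Data frame of contact events: `leg`, `onset_index`,
#'   `offset_index`, `onset_time`, `placement_x`, `placement_y`. Fewer
#'   than 2 detected cycles returns an empty frame with a warning.
#' @export
detect_contacts <- function(bout, leg,
                            method = c("extrema", "velocity_threshold", "provided"),
                            smooth_frames = 5L, prominence_frac = 0.1,
                            speed_frac = 0.3, min_dwell_frac = 0.1) {
  method <- match.arg(method)
  pr <- bout$species
  empty <- data.frame(leg = character(0), onset_index = integer(0),
                      offset_index = integer(0), onset_time = numeric(0),
                      placement_x = numeric(0), placement_y = numeric(0))
  if (method == "provided") {
    pc <- bout$provided_contacts
    pc <- pc[pc$leg == leg, , drop = FALSE]
    if (is.null(pc) || nrow(pc) < 2L) return(empty)
    return(contact_placements(bout, leg, pc$onset_index, pc$offset_index))
  }
  foot <- bout$positions[[leg]]
  bx <- rowMeans(sapply(pr$body_markers, function(m) bout$positions[[m]][, "x"]))

  if (method == "extrema") {
    s <- moving_average(foot[, "x"] - bx, smooth_frames)
    rng <- diff(range(s))
    if (rng < 1e-12) {
      warning("leg ", leg, ": no fore-aft oscillation; no contacts")
      return(empty)
    }
    prom <- prominence_frac * rng
    # first pass to estimate the cycle, then enforce half-cycle spacing
    on0 <- find_peaks(s, prom, min_spacing = 3L)
    if (length(on0) < 3L) {
      warning("leg ", leg, ": fewer than 2 cycles detected")
      return(empty)
    }
    spacing <- max(3L, floor(0.5 * stats::median(diff(on0))))
    onsets <- find_peaks(s, prom, min_spacing = spacing)
    offsets <- find_peaks(-s, prom, min_spacing = spacing)
  } else {
    vx <- central_diff(foot[, "x"], bout$t)
    vy <- central_diff(foot[, "y"], bout$t)
    speed <- moving_average(sqrt(vx^2 + vy^2), smooth_frames)
    body_speed <- stats::median(abs(moving_average(central_diff(bx, bout$t),
                                                   smooth_frames)))
    slow <- speed < speed_frac * max(body_speed, 1e-12)
    r <- rle(slow)
    ends <- cumsum(r$lengths); starts <- ends - r$lengths + 1L
    stance <- which(r$values)
    if (length(stance) < 2L) {
      warning("leg ", leg, ": fewer than 2 stance periods detected")
      return(empty)
    }
    gaps <- diff(starts[stance])
    dwell <- max(2L, floor(min_dwell_frac * stats::median(gaps) * 2))
    keep <- stance[r$lengths[stance] >= dwell]
    onsets <- starts[keep]; offsets <- ends[keep]
    if (length(onsets) < 2L) {
      warning("leg ", leg, ": fewer than 2 cycles detected")
      return(empty)
    }
    return(contact_placements(bout, leg, onsets, offsets))
  }
  # pair each onset with the first minimum after it and before the next onset
  on_keep <- integer(0); off_keep <- integer(0)
  for (i in seq_along(onsets)) {
    nxt <- if (i < length(onsets)) onsets[i + 1L] else length(bout$t) + 1L
    cand <- offsets[offsets > onsets[i] & offsets < nxt]
    if (length(cand)) {
      on_keep <- c(on_keep, onsets[i])
      off_keep <- c(off_keep, cand[1L])
    }
  }
  if (length(on_keep) < 2L) {
    warning("leg ", leg, ": fewer than 2 cycles detected")
    return(empty)
  }
  # Extrema of the foot-minus-body displacement systematically lead
  # touchdown and lag liftoff: the foot decelerates below body speed
  # before landing and only exceeds it some way into the swing. Each
  # event is therefore snapped to the nearest crossing of a low
  # foot-speed threshold (fraction of the swing-peak speed).
  vx <- central_diff(foot[, "x"], bout$t)
  vy <- central_diff(foot[, "y"], bout$t)
  speed <- moving_average(sqrt(vx^2 + vy^2), smooth_frames)
  half <- max(3L, floor(0.25 * stats::median(diff(on_keep))))
  refine <- function(i, forward) {
    win <- if (forward) i:min(i + half, length(speed))
           else i:max(i - half, 1L)
    peak <- max(speed[max(1L, i - half):min(i + half, length(speed))])
    thr <- 0.10 * peak
    hit <- which(speed[win] < thr)
    if (length(hit)) win[hit[1L]] else i
  }
  on_keep <- vapply(on_keep, refine, integer(1), forward = TRUE)
  off_keep <- vapply(off_keep, refine, integer(1), forward = FALSE)
  bad <- off_keep <= on_keep
  contact_placements(bout, leg, on_keep[!bad], off_keep[!bad])
}

contact_placements <- function(bout, leg, onsets, offsets) {
  foot <- bout$positions[[leg]]
  px <- mapply(function(a, b) mean(foot[a:b, "x"]), onsets, offsets)
  py <- mapply(function(a, b) mean(foot[a:b, "y"]), onsets, offsets)
  data.frame(leg = leg, onset_index = as.integer(onsets),
             offset_index = as.integer(offsets),
             onset_time = bout$t[onsets],
             placement_x = px, placement_y = py,
             stringsAsFactors = FALSE)
}

#' Detect contacts for all legs of a bout
#'
#' @inheritParams detect_contacts
#' @param ... Passed to [detect_contacts()].
#' @return Data frame of contact events for every leg.
#' @export
detect_all_contacts <- function(bout, method = "extrema", ...) {
  do.call(rbind, lapply(bout$species$leg_labels, function(leg)
    detect_contacts(bout, leg, method = method, ...)))
}

#' Segment gait cycles from contact events
#'
#' A gait cycle is the interval between two successive contact initiations
#' of the same limb (or successive terminations with `by =
#' "termination"`). Cycles are built independently per leg; the mean
#' fore-aft body velocity over the cycle gives `v_hat`. Cycles with
#' non-positive `v_hat` or durations beyond 3x the per-leg median are
#' dropped and logged.
#'
#' @param bout An aligned `trajectory_bout`.
#' @param contacts Contact events for all legs ([detect_all_contacts()]).
#' @param profile A `species_profile`.
#' @param by `"onset"` (default) or `"termination"`.
#' @param log Optional drop log.
#' @return Data frame of raw cycles: `leg`, `i0`, `i1`, `t0`, `t1`,
#'   `duration`, `v_hat`, `phi_swing`, end-contact placement and indices.
#' @export
segment_cycles <- function(bout, contacts, profile, by = c("onset", "termination"),
                           log = NULL) {
  by <- match.arg(by)
  pr <- profile
  bx <- rowMeans(sapply(pr$body_markers, function(m) bout$positions[[m]][, "x"]))
  out <- list()
  for (leg in pr$leg_labels) {
    cc <- contacts[contacts$leg == leg, , drop = FALSE]
    if (nrow(cc) < 2L) next
    cc <- cc[order(cc$onset_index), , drop = FALSE]
    idx <- if (by == "onset") cc$onset_index else cc$offset_index
    for (i in seq_len(nrow(cc) - 1L)) {
      i0 <- idx[i]; i1 <- idx[i + 1L]
      if (i1 - i0 < 2L) next
      dur <- bout$t[i1] - bout$t[i0]
      # mean fore-aft velocity as net displacement over duration (frame
      # differentiation at the cycle edges would smear adjacent cycles)
      vhat <- (bx[i1] - bx[i0]) / dur
      phi_swing <- (bout$t[cc$offset_index[i]] - bout$t[cc$onset_index[i]]) /
        (bout$t[cc$onset_index[i + 1L]] - bout$t[cc$onset_index[i]])
      out[[length(out) + 1L]] <- data.frame(
        leg = leg, i0 = i0, i1 = i1, t0 = bout$t[i0], t1 = bout$t[i1],
        duration = dur, v_hat = vhat, phi_swing = phi_swing,
        p_x = cc$placement_x[i + 1L], p_y = cc$placement_y[i + 1L],
        end_onset = cc$onset_index[i + 1L], stringsAsFactors = FALSE)
    }
  }
  cyc <- if (length(out)) do.call(rbind, out) else return(NULL)
  keep <- rep(TRUE, nrow(cyc))
  for (leg in unique(cyc$leg)) {
    sel <- cyc$leg == leg
    med <- stats::median(cyc$duration[sel])
    bad <- sel & (cyc$duration > 3 * med | cyc$v_hat <= 0)
    if (any(bad)) {
      keep[bad] <- FALSE
      log_drop(log, "cycle_outlier",
               sprintf("bout %s leg %s: %d cycles dropped (duration/velocity)",
                       bout$bout_id, leg, sum(bad)))
    }
  }
  cyc[keep, , drop = FALSE]
}

# linear interpolation of all columns of Y (time base t) onto xout
interp_matrix <- function(t, Y, xout) {
  i <- findInterval(xout, t, rightmost.closed = TRUE)
  i <- pmin(pmax(i, 1L), length(t) - 1L)
  w <- (xout - t[i]) / (t[i + 1L] - t[i])
  Y[i, , drop = FALSE] * (1 - w) + Y[i + 1L, , drop = FALSE] * w
}

#' Phase-normalize one gait cycle
#'
#' Marker positions and velocities (central differences computed on the
#' raw frames, before interpolation) are linearly interpolated onto `M`
#' uniform phases in `[0, 1]`, with phase 0 at the cycle's initiating
#' contact and phase 1 at the contact being predicted.
#'
#' @param bout The aligned bout the cycle came from.
#' @param cycle One row of [segment_cycles()] output.
#' @param M Phase grid size (default: the profile's `phase_grid_size`).
#' @param markers Markers to include (default body markers plus the
#'   cycle's leg).
#' @return List with `phase` (length-M grid), `Q` (M x 4B body-state
#'   matrix: x/y position and velocity per body marker) and `Q_tilde`
#'   (M x 4 matrix for the cycle's foot), or `NULL` if the cycle has
#'   fewer than 4 frames.
#' @export
phase_normalize <- function(bout, cycle, M = NULL, markers = NULL) {
  pr <- bout$species
  M <- M %||% pr$phase_grid_size
  i0 <- cycle$i0; i1 <- cycle$i1
  if (i1 - i0 + 1L < 4L) return(NULL)
  idx <- i0:i1
  tt <- bout$t[idx]
  body <- pr$body_markers
  cols <- list()
  for (m in c(body, cycle$leg)) {
    p <- bout$positions[[m]]
    cols[[paste0(m, "_x_pos")]] <- p[idx, "x"]
    cols[[paste0(m, "_y_pos")]] <- p[idx, "y"]
    # velocities from central differences over a slightly padded window so
    # the cycle edges keep centered estimates
    lo <- max(1L, i0 - 1L); hi <- min(length(bout$t), i1 + 1L)
    vx <- central_diff(p[lo:hi, "x"], bout$t[lo:hi])
    vy <- central_diff(p[lo:hi, "y"], bout$t[lo:hi])
    off <- i0 - lo
    cols[[paste0(m, "_x_vel")]] <- vx[off + seq_along(idx)]
    cols[[paste0(m, "_y_vel")]] <- vy[off + seq_along(idx)]
  }
  Y <- do.call(cbind, cols)
  phase <- seq(0, 1, length.out = M)
  xout <- cycle$t0 + phase * (cycle$t1 - cycle$t0)
  Z <- interp_matrix(tt, Y, xout)
  body_cols <- as.vector(outer(c("_x_pos", "_y_pos", "_x_vel", "_y_vel"),
                               body, function(s, m) paste0(m, s)))
  foot_cols <- paste0(cycle$leg, c("_x_pos", "_y_pos", "_x_vel", "_y_vel"))
  Qt <- Z[, foot_cols, drop = FALSE]
  colnames(Qt) <- c("foot_x_pos", "foot_y_pos", "foot_x_vel", "foot_y_vel")
  list(phase = phase, Q = Z[, sort(body_cols), drop = FALSE], Q_tilde = Qt)
}

#' Spatially normalize a phase-normalized cycle
#'
#' All positions (body and foot) and the cycle's end placement are
#' expressed relative to the last contact location of the front limb of
#' the opposite support group preceding the predicted contact. Step length
#' is the fore-aft component of the normalized placement; step width its
#' absolute lateral component.
#'
#' @param norm Output of [phase_normalize()].
#' @param cycle The cycle row.
#' @param contacts All-leg contact events of the bout.
#' @param profile A `species_profile`.
#' @return `norm` with positions shifted, plus `placement`, `ref_leg`,
#'   `ref_xy`; `NULL` if no qualifying reference contact exists.
#' @export
spatial_normalize <- function(norm, cycle, contacts, profile) {
  ref <- opposite_front_limb(profile, cycle$leg)
  rc <- contacts[contacts$leg == ref & contacts$onset_time <= cycle$t1 + 1e-9, ,
                 drop = FALSE]
  if (!nrow(rc)) return(NULL)
  rc <- rc[which.max(rc$onset_time), ]
  for (j in grep("_x_pos$", colnames(norm$Q))) norm$Q[, j] <- norm$Q[, j] - rc$placement_x
  for (j in grep("_y_pos$", colnames(norm$Q))) norm$Q[, j] <- norm$Q[, j] - rc$placement_y
  norm$Q_tilde[, "foot_x_pos"] <- norm$Q_tilde[, "foot_x_pos"] - rc$placement_x
  norm$Q_tilde[, "foot_y_pos"] <- norm$Q_tilde[, "foot_y_pos"] - rc$placement_y
  norm$placement <- c(x = cycle$p_x - rc$placement_x,
                      y = cycle$p_y - rc$placement_y)
  norm$ref_leg <- ref
  norm$ref_xy <- c(rc$placement_x, rc$placement_y)
  norm
}

#' Build a phase- and spatially-normalized cycle set from bouts
#'
#' Runs contact detection, segmentation, phase normalization and spatial
#' normalization over a list of aligned bouts and collects the result into
#' a `gait_cycles` object: a meta table plus dense arrays `Q` (cycles x
#' phases x body channels) and `Q_tilde` (cycles x phases x 4 foot
#' channels).
#'
#' @param bouts List of aligned `trajectory_bout`s (one animal).
#' @param profile A `species_profile`.
#' @param animal Animal/subject label.
#' @param method Contact detection method.
#' @param M Phase grid size (default: profile's).
#' @param by Segmentation anchor (`"onset"` or `"termination"`).
#' @param log Optional drop log.
#' @param contacts_list Optional pre-computed contacts per bout.
#' @return A `gait_cycles` object.
#' @export
build_cycles <- function(bouts, profile, animal = "a1", method = "extrema",
                         M = NULL, by = "onset", log = NULL,
                         contacts_list = NULL) {
  M <- M %||% profile$phase_grid_size
  meta <- list(); Qs <- list(); Qts <- list()
  for (bi in seq_along(bouts)) {
    bout <- bouts[[bi]]
    contacts <- if (!is.null(contacts_list)) contacts_list[[bi]] else
      detect_all_contacts(bout, method = method)
    if (is.null(contacts) || !nrow(contacts)) next
    cyc <- segment_cycles(bout, contacts, profile, by = by, log = log)
    if (is.null(cyc) || !nrow(cyc)) next
    counter <- stats::setNames(rep(0L, profile$n_legs), profile$leg_labels)
    for (r in seq_len(nrow(cyc))) {
      cycle <- cyc[r, ]
      norm <- phase_normalize(bout, cycle, M = M)
      if (is.null(norm)) {
        log_drop(log, "too_few_frames",
                 sprintf("bout %s leg %s cycle at t=%.3f", bout$bout_id,
                         cycle$leg, cycle$t0))
        next
      }
      norm <- spatial_normalize(norm, cycle, contacts, profile)
      if (is.null(norm)) {
        log_drop(log, "no_reference_contact",
                 sprintf("bout %s leg %s cycle at t=%.3f", bout$bout_id,
                         cycle$leg, cycle$t0))
        next
      }
      counter[cycle$leg] <- counter[cycle$leg] + 1L
      meta[[length(meta) + 1L]] <- data.frame(
        animal = animal, bout = bout$bout_id, leg = cycle$leg,
        cycle_idx = counter[cycle$leg], t0 = cycle$t0, t1 = cycle$t1,
        duration = cycle$duration, v_hat = cycle$v_hat,
        phi_swing = cycle$phi_swing,
        p_x = norm$placement["x"], p_y = norm$placement["y"],
        ref_leg = norm$ref_leg,
        ref_side = leg_side(profile, norm$ref_leg),
        stringsAsFactors = FALSE)
      Qs[[length(Qs) + 1L]] <- norm$Q
      Qts[[length(Qts) + 1L]] <- norm$Q_tilde
    }
  }
  if (!length(meta)) return(NULL)
  meta <- do.call(rbind, meta)
  rownames(meta) <- NULL
  n <- nrow(meta)
  Q <- array(NA_real_, c(n, M, ncol(Qs[[1]])),
             dimnames = list(NULL, NULL, colnames(Qs[[1]])))
  Qt <- array(NA_real_, c(n, M, 4L),
              dimnames = list(NULL, NULL, colnames(Qts[[1]])))
  for (i in seq_len(n)) {
    Q[i, , ] <- Qs[[i]]
    Qt[i, , ] <- Qts[[i]]
  }
  structure(list(meta = meta, Q = Q, Q_tilde = Qt,
                 phase = seq(0, 1, length.out = M), profile = profile),
            class = "gait_cycles")
}

#' Combine gait cycle sets from several animals
#'
#' @param ... `gait_cycles` objects (or a single list of them).
#' @return A pooled `gait_cycles` object.
#' @export
combine_cycles <- function(...) {
  xs <- list(...)
  if (length(xs) == 1L && !inherits(xs[[1]], "gait_cycles")) xs <- xs[[1]]
  xs <- Filter(Negate(is.null), xs)
  if (!length(xs)) return(NULL)
  meta <- do.call(rbind, lapply(xs, `[[`, "meta"))
  rownames(meta) <- NULL
  n <- nrow(meta)
  M <- dim(xs[[1]]$Q)[2]
  Q <- array(NA_real_, c(n, M, dim(xs[[1]]$Q)[3]),
             dimnames = dimnames(xs[[1]]$Q))
  Qt <- array(NA_real_, c(n, M, 4L), dimnames = dimnames(xs[[1]]$Q_tilde))
  at <- 0L
  for (x in xs) {
    k <- nrow(x$meta)
    Q[at + seq_len(k), , ] <- x$Q
    Qt[at + seq_len(k), , ] <- x$Q_tilde
    at <- at + k
  }
  structure(list(meta = meta, Q = Q, Q_tilde = Qt, phase = xs[[1]]$phase,
                 profile = xs[[1]]$profile), class = "gait_cycles")
}

#' @export
print.gait_cycles <- function(x, ...) {
  cat("<gait_cycles>", nrow(x$meta), "cycles,",
      length(unique(x$meta$animal)), "animal(s),",
      length(unique(x$meta$leg)), "leg(s), M =", length(x$phase), "\n")
  invisible(x)
}
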