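key_al <- function(animal, leg) paste(animal, leg, sep = "|")

#' Fit the linear velocity model for step length or width
#'
#' Ordinary least squares of the step geometry on the cycle's mean
#' fore-aft velocity, per animal and per leg: `target = b0 + b1 * v_hat`.
#' Step length is the signed fore-aft placement component; step width the
#' absolute lateral component.
#'
#' @param cycles A `gait_cycles` object.
#' @param target `"length"` or `"width"`.
#' @param min_cycles Minimum cycles per animal/leg (default 10).
#' @return Data frame: animal, leg, beta0, beta1, se1, p_slope, r2, n.
#' @export
fit_linear_velocity_model <- function(cycles, target = c("length", "width"),
                                      min_cycles = 10L) {
  target <- match.arg(target)
  meta <- cycles$meta
  y_all <- if (target == "length") meta$p_x else abs(meta$p_y)
  out <- list()
  for (an in unique(meta$animal)) for (leg in unique(meta$leg)) {
    sel <- meta$animal == an & meta$leg == leg
    if (sum(sel) < min_cycles) next
    v <- meta$v_hat[sel]; y <- y_all[sel]
    if (stats::var(v) < 1e-18 * mean(v)^2)
      stop("degenerate v_hat (zero variance) for ", an, "/", leg)
    fit <- stats::lm(y ~ v)
    sm <- summary(fit)
    out[[length(out) + 1L]] <- data.frame(
      animal = an, leg = leg,
      beta0 = unname(stats::coef(fit)[1]), beta1 = unname(stats::coef(fit)[2]),
      se1 = sm$coefficients[2, 2], p_slope = sm$coefficients[2, 4],
      r2 = sm$r.squared, n = sum(sel), stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}

#' Fit the exponential duration model
#'
#' Nonlinear least squares of cycle duration on velocity,
#' `d = b0 * exp(-b1 * (v - b2)) + b3`, per animal and per leg, with
#' multi-start initialization: `b3` from the high-speed quartile mean,
#' `b0` from the low/high quartile contrast, `b2` at the median velocity,
#' `b1` from the log-slope (tried at three scales). The raw
#' parameterization is degenerate (`b0` and `b2` trade off through
#' `b0 * exp(b1 * b2)`), so the identifiable amplitude at the median
#' velocity is reported alongside. Non-convergence after all starts flags
#' the fit; deviations then fall back to a smoothing-spline duration
#' model.
#'
#' @param cycles A `gait_cycles` object.
#' @param min_cycles Minimum cycles per animal/leg (default 20).
#' @return List of per-animal/leg fits (class `duration_fit` each):
#'   `beta` (b0..b3), `se`, `amplitude_at_median_v`, `converged`,
#'   `fallback` (smooth.spline or NULL), `v_range`.
#' @export
fit_exponential_duration_model <- function(cycles, min_cycles = 20L) {
  meta <- cycles$meta
  out <- list()
  for (an in unique(meta$animal)) for (leg in unique(meta$leg)) {
    sel <- meta$animal == an & meta$leg == leg
    if (sum(sel) < min_cycles) next
    out[[key_al(an, leg)]] <- fit_exp_duration_one(meta$v_hat[sel],
                                                   meta$duration[sel],
                                                   animal = an, leg = leg)
  }
  out
}

fit_exp_duration_one <- function(v, d, animal = NA, leg = NA) {
  if (stats::var(v) < 1e-18 * mean(v)^2) stop("degenerate v_hat range")
  # the 4-parameter form b0*exp(-b1*(v-b2)) + b3 is exactly degenerate
  # (b0 and b2 trade off through b0*exp(b1*b2)), so the identifiable
  # reduced form a0*exp(-b1*(v-vmed)) + b3 is fitted, anchoring b2 at the
  # median velocity; the 4-parameter convention is reported with b2 = vmed
  vmed <- stats::median(v)
  vc <- v - vmed
  qs <- stats::quantile(v, c(0.25, 0.5, 0.75))
  b3_0 <- mean(d[v >= qs[3]])
  a0_0 <- max(stats::median(d) - b3_0, 0.1 * diff(range(d)), 1e-8)
  pos <- d - min(d) + 1e-8
  sl <- tryCatch(unname(stats::coef(stats::lm(log(pos) ~ v))[2]),
                 error = function(e) NA_real_)
  b1_0 <- if (is.finite(sl) && sl < 0) -sl else 1 / stats::sd(v)
  best <- NULL
  for (s in c(1, 0.3, 3)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(d ~ a0 * exp(-b1 * vc) + b3,
                        start = list(a0 = a0_0, b1 = b1_0 * s, b3 = b3_0),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (!is.null(fit)) {
      rss <- sum(stats::resid(fit)^2)
      if (is.null(best) || rss < best$rss) best <- list(fit = fit, rss = rss)
    }
  }
  if (is.null(best)) {
    sp <- stats::smooth.spline(v, d, df = min(4, length(unique(v)) - 1))
    return(structure(list(animal = animal, leg = leg, beta = rep(NA_real_, 4),
                          se = rep(NA_real_, 4), converged = FALSE,
                          fallback = sp, v_range = range(v), n = length(v),
                          amplitude_at_median_v = NA_real_),
                     class = "duration_fit"))
  }
  co <- stats::coef(best$fit)
  se3 <- tryCatch(summary(best$fit)$coefficients[, 2],
                  error = function(e) stats::setNames(rep(NA_real_, 3),
                                                      names(co)))
  beta <- c(unname(co["a0"]), unname(co["b1"]), vmed, unname(co["b3"]))
  se <- c(unname(se3["a0"]), unname(se3["b1"]), NA_real_, unname(se3["b3"]))
  structure(list(animal = animal, leg = leg, beta = beta, se = se,
                 converged = TRUE, fallback = NULL,
                 v_range = range(v), n = length(v),
                 amplitude_at_median_v = beta[1]),
            class = "duration_fit")
}

predict_duration <- function(fit, v) {
  if (fit$converged)
    fit$beta[1] * exp(-fit$beta[2] * (v - fit$beta[3])) + fit$beta[4]
  else stats::predict(fit$fallback, v)$y
}

#' Fit the velocity-conditioned nominal gait pattern
#'
#' For every phase on the grid and every state channel (body and foot,
#' positions and velocities), the channel is regressed on the cycle
#' velocity `v_hat` with an intercept; the fitted values define the
#' nominal pattern `Q*_v(phi)`. Body-state errors downstream are
#' deviations from this velocity-dependent nominal, not from the average
#' behavior. With no velocity dependence the nominal reduces to the
#' per-phase mean.
#'
#' @param cycles A `gait_cycles` object.
#' @param min_cycles Minimum cycles per animal/leg (default 30).
#' @return List keyed by `animal|leg` with elements `coef_Q` and
#'   `coef_Qt` (arrays 2 x M x channels: intercept and velocity slope)
#'   and `v_range`.
#' @export
fit_nominal_pattern <- function(cycles, min_cycles = 30L) {
  meta <- cycles$meta
  M <- length(cycles$phase)
  out <- list()
  for (an in unique(meta$animal)) for (leg in unique(meta$leg)) {
    sel <- which(meta$animal == an & meta$leg == leg)
    if (length(sel) < min_cycles) next
    v <- meta$v_hat[sel]
    X <- cbind(1, v)
    XtXi <- solve(crossprod(X))
    fit_arr <- function(A) {
      nC <- dim(A)[3]
      Y <- matrix(A[sel, , ], length(sel), M * nC)
      B <- XtXi %*% crossprod(X, Y)          # 2 x (M*nC)
      array(B, c(2, M, nC),
            dimnames = list(c("intercept", "slope"), NULL, dimnames(A)[[3]]))
    }
    out[[key_al(an, leg)]] <- list(coef_Q = fit_arr(cycles$Q),
                                   coef_Qt = fit_arr(cycles$Q_tilde),
                                   v_range = range(v), n = length(sel))
  }
  out
}

#' Fit the full feedforward module
#'
#' Convenience wrapper fitting, per animal and leg: the linear length and
#' width models, signed placement models (used for placement deviations;
#' the lateral placement keeps its sign so deviations carry the correction
#' direction), the exponential duration model, and the per-phase nominal
#' pattern.
#'
#' @param cycles A `gait_cycles` object.
#' @param min_cycles Minimum cycles per animal/leg (default 30).
#' @return An object of class `feedforward_fit`.
#' @export
fit_feedforward <- function(cycles, min_cycles = 30L) {
  meta <- cycles$meta
  lin <- function(y, sel) {
    v <- meta$v_hat[sel]
    fit <- stats::lm(y[sel] ~ v)
    list(beta = unname(stats::coef(fit)),
         se = unname(summary(fit)$coefficients[, 2]))
  }
  by <- list()
  for (an in unique(meta$animal)) for (leg in unique(meta$leg)) {
    sel <- meta$animal == an & meta$leg == leg
    if (sum(sel) < min_cycles) next
    by[[key_al(an, leg)]] <- list(
      animal = an, leg = leg, n = sum(sel),
      px = lin(meta$p_x, sel),
      py = lin(meta$p_y, sel),
      width = lin(abs(meta$p_y), sel),
      duration = fit_exp_duration_one(meta$v_hat[sel], meta$duration[sel],
                                      animal = an, leg = leg),
      v_range = range(meta$v_hat[sel]))
  }
  nominal <- fit_nominal_pattern(cycles, min_cycles = min_cycles)
  structure(list(by = by, nominal = nominal,
                 length_fits = fit_linear_velocity_model(cycles, "length",
                                                         min_cycles = min_cycles),
                 width_fits = fit_linear_velocity_model(cycles, "width",
                                                        min_cycles = min_cycles)),
            class = "feedforward_fit")
}

#' Compute deviations from the fitted feedforward module
#'
#' Body-state errors `dQ(phi) = Q(phi) - Q*_v(phi)`, foot-state errors
#' `dQt`, placement deviations `dP = P - f(v_hat)` (signed, both
#' components), and duration deviations. Cycles whose velocity falls more
#' than 20% outside the fitted range are computed but flagged
#' `extrapolated`. Bookkeeping (animal, leg, bout, within-bout cycle
#' order) is preserved.
#'
#' @param cycles A `gait_cycles` object.
#' @param ff A `feedforward_fit` on the same animals.
#' @return An object of class `deviation_set`: `meta` (with `dP_x`,
#'   `dP_y`, `d_duration`, `extrapolated`), arrays `dQ`, `dQt`, `phase`,
#'   `profile`.
#' @export
compute_deviations <- function(cycles, ff) {
  meta <- cycles$meta
  n <- nrow(meta)
  M <- length(cycles$phase)
  dQ <- cycles$Q; dQt <- cycles$Q_tilde
  dP_x <- dP_y <- dDur <- rep(NA_real_, n)
  extrap <- rep(FALSE, n)
  keep <- rep(FALSE, n)
  for (k in names(ff$nominal)) {
    info <- ff$by[[k]]
    sel <- which(meta$animal == info$animal & meta$leg == info$leg)
    if (!length(sel)) next
    keep[sel] <- TRUE
    v <- meta$v_hat[sel]
    nom <- ff$nominal[[k]]
    for (A in c("Q", "Qt")) {
      co <- if (A == "Q") nom$coef_Q else nom$coef_Qt
      src <- if (A == "Q") cycles$Q else cycles$Q_tilde
      nC <- dim(co)[3]
      pred <- matrix(rep(as.vector(co[1, , ]), each = length(sel)),
                     length(sel), M * nC) +
        outer(v, as.vector(co[2, , ]))
      dev <- matrix(src[sel, , ], length(sel), M * nC) - pred
      if (A == "Q") dQ[sel, , ] <- array(dev, c(length(sel), M, nC))
      else dQt[sel, , ] <- array(dev, c(length(sel), M, nC))
    }
    dP_x[sel] <- meta$p_x[sel] - (info$px$beta[1] + info$px$beta[2] * v)
    dP_y[sel] <- meta$p_y[sel] - (info$py$beta[1] + info$py$beta[2] * v)
    dDur[sel] <- meta$duration[sel] - predict_duration(info$duration, v)
    rng <- info$v_range
    pad <- 0.2 * diff(rng)
    extrap[sel] <- v < rng[1] - pad | v > rng[2] + pad
  }
  meta$dP_x <- dP_x; meta$dP_y <- dP_y; meta$d_duration <- dDur
  meta$extrapolated <- extrap
  structure(list(meta = meta[keep, , drop = FALSE],
                 dQ = dQ[keep, , , drop = FALSE],
                 dQt = dQt[keep, , , drop = FALSE],
                 phase = cycles$phase, profile = cycles$profile),
            class = "deviation_set")
}

#' @export
print.deviation_set <- function(x, ...) {
  cat("<deviation_set>", nrow(x$meta), "cycles,",
      length(unique(x$meta$animal)), "animal(s)\n")
  invisible(x)
}

#' Test independence of contact-timing and step-width deviations
#'
#' Chatterjee's xi between duration deviations and step-width deviations
#' (deviations of `|p_y|` from the fitted width law), per leg, pooling
#' animals. A feedforward-only account in which width variability stems
#' from timing variability predicts dependence here.
#'
#' @param dev A `deviation_set`.
#' @param ff The `feedforward_fit` used to build it.
#' @param min_n Minimum paired deviations per leg (default 30).
#' @return Data frame: leg, xi, p, n.
#' @export
timing_width_independence <- function(dev, ff, min_n = 30L) {
  meta <- dev$meta
  # width deviation against the fitted |p_y| law
  dW <- rep(NA_real_, nrow(meta))
  for (k in names(ff$by)) {
    info <- ff$by[[k]]
    sel <- meta$animal == info$animal & meta$leg == info$leg
    dW[sel] <- abs(meta$p_y[sel]) -
      (info$width$beta[1] + info$width$beta[2] * meta$v_hat[sel])
  }
  out <- list()
  for (leg in unique(meta$leg)) {
    sel <- meta$leg == leg & is.finite(meta$d_duration) & is.finite(dW)
    if (sum(sel) < min_n) next
    xi <- chatterjee_xi(meta$d_duration[sel], dW[sel])
    out[[length(out) + 1L]] <- data.frame(leg = leg, xi = xi$xi, p = xi$p,
                                          n = xi$n, stringsAsFactors = FALSE)
  }
  do.call(rbind, out)
}
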