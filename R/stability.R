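#' Fit a Poincare return map on cycle-to-cycle body-state deviations
#'
#' Linear map between body-state deviations sampled at gait fraction
#' `phi0` on consecutive cycles of the same leg (within the same bout and
#' animal). The map is fitted forward in time: the next cycle's deviation
#' is the response and the current cycle's the predictor, so eigenvalue
#' moduli below 1 indicate a stable gait. The literal backward-direction
#' regression (earlier state on later state) is available via
#' `direction = "backward"`; note the eigenvalues of the two fitted maps
#' are not reciprocal under noise. Channels with (near-)zero variance are
#' dropped before fitting; residual rank deficiency triggers a tiny
#' ridge penalty (flagged).
#'
#' @param dev A `deviation_set`.
#' @param phi0 Sampling phase (default 0.75).
#' @param leg Leg whose cycles index the map (default: the profile's
#'   first leg).
#' @param animal Optional animal subset (default: all, pairs never cross
#'   animals).
#' @param direction `"forward"` (default) or `"backward"`.
#' @return Object of class `return_map_fit`: `K` (square matrix on the
#'   retained channels), `eigenvalues`, `spectral_radius`, `n_pairs`,
#'   `channels`, `ridged`.
#' @export
fit_return_map <- function(dev, phi0 = 0.75, leg = NULL, animal = NULL,
                           direction = c("forward", "backward")) {
  direction <- match.arg(direction)
  leg <- leg %||% dev$profile$leg_labels[1]
  meta <- dev$meta
  rows <- which(meta$leg == leg & !meta$extrapolated)
  if (!is.null(animal)) rows <- rows[meta$animal[rows] %in% animal]
  m <- phase_index(dev$phase, phi0)
  # consecutive-cycle pairs within animal and bout
  key <- paste(meta$animal[rows], meta$bout[rows])
  idx_now <- idx_next <- integer(0)
  for (k in unique(key)) {
    rr <- rows[key == k]
    rr <- rr[order(meta$cycle_idx[rr])]
    ci <- meta$cycle_idx[rr]
    j <- which(diff(ci) == 1L)
    idx_now <- c(idx_now, rr[j]); idx_next <- c(idx_next, rr[j + 1L])
  }
  X <- dev$dQ[idx_now, m, , drop = TRUE]
  Y <- dev$dQ[idx_next, m, , drop = TRUE]
  if (is.null(dim(X))) { X <- matrix(X, ncol = dim(dev$dQ)[3]); Y <- matrix(Y, ncol = dim(dev$dQ)[3]) }
  channels <- dimnames(dev$dQ)[[3]]
  colnames(X) <- colnames(Y) <- channels
  if (direction == "backward") { tmp <- X; X <- Y; Y <- tmp }
  dim_state <- ncol(X)
  if (nrow(X) < 10 * dim_state)
    warning("only ", nrow(X), " consecutive pairs for a ", dim_state,
            "-dimensional return map")
  keep <- apply(X, 2, function(z) stats::var(z) > 1e-20 * (mean(z)^2 + 1))
  Xk <- X[, keep, drop = FALSE]; Yk <- Y[, keep, drop = FALSE]
  Xc <- cbind(1, Xk)
  ridged <- FALSE
  qrX <- qr(Xc)
  if (qrX$rank < ncol(Xc)) {
    ridged <- TRUE
    XtX <- crossprod(Xc)
    lam <- 1e-8 * mean(diag(XtX))
    B <- solve(XtX + lam * diag(ncol(Xc)), crossprod(Xc, Yk))
  } else {
    B <- qr.coef(qrX, Yk)
  }
  K <- t(B[-1L, , drop = FALSE])   # rows: response channels
  ev <- eigen(K, only.values = TRUE)$values
  structure(list(K = K, eigenvalues = ev,
                 spectral_radius = max(Mod(ev)), phi0 = dev$phase[m],
                 n_pairs = nrow(X), channels = channels[keep],
                 direction = direction, leg = leg, ridged = ridged),
            class = "return_map_fit")
}

#' @export
print.return_map_fit <- function(x, ...) {
  cat(sprintf("<return_map_fit> %s leg %s @ phi=%.2f: rho = %.3f (%d pairs, %d channels)\n",
              x$direction, x$leg, x$phi0, x$spectral_radius, x$n_pairs,
              length(x$channels)))
  invisible(x)
}

#' Relate placement deviations to subsequent error reduction
#'
#' For each consecutive same-leg cycle pair, the error reduction around
#' the shared contact is the mean absolute lateral body-state error over
#' the half-cycle before the contact (phases 0.5-1 of the first cycle)
#' minus that over the half-cycle after it (phases 0-0.5 of the next
#' cycle). A stabilizing role of placement predicts a positive regression
#' slope of this reduction on the magnitude of the lateral placement
#' deviation at the contact.
#'
#' @param dev A `deviation_set`.
#' @param leg Leg label(s) (default: all legs, pooled).
#' @param min_pairs Minimum usable contacts (default 30).
#' @return List of class `error_reduction_result`: `slope`, `p`, `n`,
#'   `delta_error`, `abs_dp`.
#' @export
error_reduction_analysis <- function(dev, leg = NULL, min_pairs = 30L) {
  meta <- dev$meta
  legs <- leg %||% unique(meta$leg)
  ypos <- grep("_y_pos$", dimnames(dev$dQ)[[3]])
  M <- length(dev$phase)
  pre_idx <- which(dev$phase >= 0.5)
  post_idx <- which(dev$phase <= 0.5)
  err_y <- abs(apply(dev$dQ[, , ypos, drop = FALSE], c(1, 2), mean))
  pre_mean <- rowMeans(err_y[, pre_idx, drop = FALSE])
  post_mean <- rowMeans(err_y[, post_idx, drop = FALSE])
  d_err <- abs_dp <- numeric(0)
  for (lg in legs) {
    rows <- which(meta$leg == lg & !meta$extrapolated)
    key <- paste(meta$animal[rows], meta$bout[rows])
    for (k in unique(key)) {
      rr <- rows[key == k]
      rr <- rr[order(meta$cycle_idx[rr])]
      j <- which(diff(meta$cycle_idx[rr]) == 1L)
      if (!length(j)) next
      d_err <- c(d_err, pre_mean[rr[j]] - post_mean[rr[j + 1L]])
      abs_dp <- c(abs_dp, abs(meta$dP_y[rr[j]]))
    }
  }
  if (length(d_err) < min_pairs)
    stop("only ", length(d_err), " extendable contacts (< ", min_pairs, ")")
  if (stats::var(abs_dp) == 0 || stats::var(d_err) == 0)
    stop("degenerate error-reduction inputs (zero variance)")
  fit <- stats::lm(d_err ~ abs_dp)
  sm <- summary(fit)
  structure(list(slope = unname(stats::coef(fit)[2]),
                 p = sm$coefficients[2, 4], n = length(d_err),
                 delta_error = d_err, abs_dp = abs_dp),
            class = "error_reduction_result")
}

#' Lagged correlations of lateral placement deviations
#'
#' Pearson correlation between the lateral placement deviation of a leg
#' at cycle t and at cycle t+N, for lookup horizons N = 0..N_max. Pairs
#' never span bout (or animal) boundaries, and only cycles exactly N
#' apart in within-bout order are paired.
#'
#' @param dev A `deviation_set` (or a list of numeric sequences via
#'   `sequences`).
#' @param leg Leg label, or several (sequences stay separated per leg;
#'   pooling legs sharpens the estimate when legs share one timescale).
#' @param N_max Maximum horizon (default 8).
#' @param sequences Optional list of numeric per-bout sequences,
#'   bypassing `dev`/`leg`.
#' @return Data frame of class `lag_profile`: `lag`, `r`, `n_pairs`, with
#'   the sequences attached as an attribute for bootstrap use.
#' @export
lag_correlation_profile <- function(dev = NULL, leg = NULL, N_max = 8L,
                                    sequences = NULL) {
  seq_groups <- NULL
  if (is.null(sequences)) {
    meta <- dev$meta
    rows <- which(meta$leg %in% leg)
    key <- paste(meta$animal[rows], meta$bout[rows], meta$leg[rows])
    sequences <- lapply(split(rows, key), function(rr) {
      rr <- rr[order(meta$cycle_idx[rr])]
      # re-expand onto the cycle-index grid so dropped cycles leave NA gaps
      ci <- meta$cycle_idx[rr]
      s <- rep(NA_real_, max(ci))
      s[ci] <- meta$dP_y[rr]
      s
    })
    # bootstrap unit: the bout. Legs of one bout share the same body-error
    # realization, so their sequences resample together.
    bout_of <- vapply(strsplit(names(sequences), " "), function(p)
      paste(p[1], p[2]), character(1))
    seq_groups <- split(seq_along(sequences), bout_of)
  }
  lags <- 0:N_max
  r <- n_pairs <- rep(NA_real_, length(lags))
  for (i in seq_along(lags)) {
    N <- lags[i]
    a <- b <- numeric(0)
    for (s in sequences) {
      if (length(s) <= N) next
      a <- c(a, s[seq_len(length(s) - N)])
      b <- c(b, s[seq_len(length(s) - N) + N])
    }
    ok <- is.finite(a) & is.finite(b)
    if (sum(ok) >= 3L) {
      r[i] <- if (N == 0L) 1 else stats::cor(a[ok], b[ok])
      n_pairs[i] <- sum(ok)
    }
  }
  keep <- !is.na(r)
  if (!all(keep))
    warning("insufficient consecutive data: lags truncated at N = ",
            max(lags[keep]))
  out <- data.frame(lag = lags[keep], r = r[keep], n_pairs = n_pairs[keep])
  attr(out, "sequences") <- sequences
  attr(out, "seq_groups") <- seq_groups
  class(out) <- c("lag_profile", class(out))
  out
}

fit_exp_decay <- function(lag, r, offset = TRUE) {
  # r(N) = r0 * exp(-N / tau) [+ c0], N >= 1. The optional additive
  # offset absorbs the O(1/n) depression of pooled lagged correlations
  # caused by per-individual in-sample centering of the placement
  # deviations; without it the timescale is systematically
  # underestimated at a few hundred cycles per individual.
  sel <- lag >= 1 & is.finite(r)
  lag <- lag[sel]; r <- r[sel]
  if (length(lag) < 3L) stop("need at least 3 lags")
  if (r[1] <= 0) return(list(r0 = 0, tau = 0, c0 = 0, flag = "nonpositive_r1"))
  pos <- r > 1e-12
  tau0 <- if (sum(pos) >= 2) {
    sl <- unname(stats::coef(stats::lm(log(r[pos]) ~ lag[pos]))[2])
    if (is.finite(sl) && sl < 0) -1 / sl else 1
  } else 1
  r0_0 <- min(r[1] * exp(lag[1] / tau0), 1)
  fit <- if (offset && length(lag) >= 4L) tryCatch(
    minpack.lm::nlsLM(r ~ r0 * exp(-lag / tau) + c0,
                      start = list(r0 = r0_0, tau = max(tau0, 1e-3),
                                   c0 = -1e-4),
                      lower = c(r0 = 0, tau = 1e-6, c0 = -0.2),
                      upper = c(r0 = 1.5, tau = 1e3, c0 = 0),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL) else NULL
  if (is.null(fit)) {
    fit <- tryCatch(
      minpack.lm::nlsLM(r ~ r0 * exp(-lag / tau),
                        start = list(r0 = r0_0, tau = max(tau0, 1e-3)),
                        lower = c(r0 = -1, tau = 1e-6),
                        upper = c(r0 = 1.5, tau = 1e3),
                        control = minpack.lm::nls.lm.control(maxiter = 200)),
      error = function(e) NULL)
    if (is.null(fit)) return(list(r0 = r0_0, tau = tau0, c0 = 0,
                                  flag = "nls_failed"))
  }
  co <- stats::coef(fit)
  list(r0 = unname(co["r0"]), tau = unname(co["tau"]),
       c0 = unname(co["c0"] %||% 0), flag = "ok")
}

#' Fit the exponential decay timescale of lagged correlations
#'
#' Nonlinear least squares of `r(N) = r0 * exp(-N / tau)` over N >= 1,
#' with a bootstrap (resampling bouts with replacement, preserving serial
#' structure within bouts and keeping the legs of a bout together) for
#' the confidence interval of `tau`. By default the fit carries a free
#' non-positive additive offset that absorbs the O(1/n) depression of
#' pooled lagged correlations induced by per-individual in-sample
#' centering of the placement deviations (the artifact can only depress,
#' so the offset is sign-constrained); `offset = FALSE` gives the pure
#' two-parameter decay. A non-positive lag-1 correlation is reported as `tau = 0` (no
#' measurable persistence).
#'
#' @param profile A `lag_profile` from [lag_correlation_profile()].
#' @param n_boot Bootstrap resamples (default 10000).
#' @param ci_level Central CI level (default 0.90).
#' @param offset Include the additive offset term (default `TRUE`).
#' @param seed Optional seed for the bootstrap.
#' @return Object of class `timescale_fit`: `r0`, `tau`, `tau_ci`, `c0`,
#'   `flag`, `n_boot`.
#' @export
fit_decay_timescale <- function(profile, n_boot = 10000L, ci_level = 0.90,
                                offset = TRUE, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  est <- fit_exp_decay(profile$lag, profile$r, offset = offset)
  seqs <- attr(profile, "sequences")
  groups <- attr(profile, "seq_groups") %||%
    as.list(seq_along(seqs %||% list()))
  N_max <- max(profile$lag)
  tau_b <- rep(NA_real_, n_boot)
  if (!is.null(seqs) && length(seqs) >= 1L && n_boot > 0L) {
    for (b in seq_len(n_boot)) {
      pick <- unlist(groups[sample(length(groups), replace = TRUE)])
      pb <- tryCatch(
        suppressWarnings(lag_correlation_profile(sequences = seqs[pick],
                                                 N_max = N_max)),
        error = function(e) NULL)
      if (is.null(pb) || nrow(pb) < 4L) next
      tb <- tryCatch(fit_exp_decay(pb$lag, pb$r, offset = offset),
                     error = function(e) NULL)
      if (!is.null(tb)) tau_b[b] <- tb$tau
    }
  }
  alpha <- (1 - ci_level) / 2
  ci <- if (any(is.finite(tau_b)))
    stats::quantile(tau_b, c(alpha, 1 - alpha), na.rm = TRUE, names = FALSE)
  else c(NA_real_, NA_real_)
  structure(list(r0 = est$r0, tau = est$tau, tau_ci = ci, c0 = est$c0,
                 flag = est$flag, ci_level = ci_level, n_boot = n_boot,
                 tau_boot = tau_b),
            class = "timescale_fit")
}

#' @export
print.timescale_fit <- function(x, ...) {
  cat(sprintf("<timescale_fit> tau = %.3f cycles (r0 = %.3f), %d%% CI [%.3f, %.3f]%s\n",
              x$tau, x$r0, round(100 * x$ci_level), x$tau_ci[1], x$tau_ci[2],
              if (x$flag != "ok") paste0(" [", x$flag, "]") else ""))
  invisible(x)
}
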