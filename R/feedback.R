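phase_index <- function(phase_grid, phi) {
  which.min(abs(phase_grid - phi))
}

# rows of the deviation set for one animal/leg, excluding extrapolated cycles
dev_rows <- function(dev, animal, leg) {
  which(dev$meta$animal == animal & dev$meta$leg == leg &
          !dev$meta$extrapolated)
}

#' Fit the body-state-error feedback map at one phase
#'
#' Multiple OLS of the placement deviation on the body-state error vector
#' at gait fraction `phi`, with intercept:
#' `dP = g0 + sum_i g_i dQ_i(phi)`. The explained variance is the
#' in-sample coefficient of determination of the normal-equations
#' estimator. Zero-variance predictors are dropped; a remaining rank
#' deficiency triggers a tiny ridge penalty (flagged).
#'
#' @param dev A `deviation_set`.
#' @param phi Gait fraction in `[0, 1]` (snapped to the grid).
#' @param direction `"lateral"` (dP_y) or `"fore_aft"` (dP_x).
#' @param animal,leg Subset selectors.
#' @param rows Optional explicit row subset (overrides animal/leg).
#' @return An object of class `feedback_fit`: `gains` (intercept +
#'   per-channel coefficients), `r2`, `n`, `phi`, `direction`, `ridged`,
#'   `dropped`.
#' @export
fit_error_map <- function(dev, phi, direction = c("lateral", "fore_aft"),
                          animal = NULL, leg = NULL, rows = NULL) {
  direction <- match.arg(direction)
  fit_map_at(dev, dev$dQ, phi, direction, animal, leg, rows, "body_state")
}

#' Fit the foot-kinematics baseline map at one phase
#'
#' Identical regression with the swinging foot's own position and
#' velocity deviations as predictors; controls for information already
#' present in the foot trajectory. As `phi -> 1` the foot reaches its
#' placement, so the baseline explained variance tends to 1 by geometry.
#'
#' @inheritParams fit_error_map
#' @return A `feedback_fit`.
#' @export
fit_baseline_map <- function(dev, phi, direction = c("lateral", "fore_aft"),
                             animal = NULL, leg = NULL, rows = NULL) {
  direction <- match.arg(direction)
  fit_map_at(dev, dev$dQt, phi, direction, animal, leg, rows, "baseline")
}

fit_map_at <- function(dev, A, phi, direction, animal, leg, rows, model) {
  if (is.null(rows)) {
    rows <- seq_len(nrow(dev$meta))
    if (!is.null(animal)) rows <- rows[dev$meta$animal[rows] %in% animal]
    if (!is.null(leg)) rows <- rows[dev$meta$leg[rows] %in% leg]
    rows <- rows[!dev$meta$extrapolated[rows]]
  }
  m <- phase_index(dev$phase, phi)
  X <- A[rows, m, , drop = TRUE]
  if (is.null(dim(X))) X <- matrix(X, ncol = dim(A)[3])
  colnames(X) <- dimnames(A)[[3]]
  y <- if (direction == "lateral") dev$meta$dP_y[rows] else dev$meta$dP_x[rows]
  N <- ncol(X)
  if (length(y) < 5 * (N + 1))
    warning("n = ", length(y), " below 5*(N+1) = ", 5 * (N + 1))
  fit <- ols_map(X, y)
  structure(list(gains = c(intercept = fit$intercept, fit$coef),
                 se = fit$se, vcov = fit$vcov,
                 r2 = fit$r2, n = fit$n, phi = dev$phase[m],
                 direction = direction, model = model,
                 ridged = fit$ridged, dropped = fit$dropped),
            class = "feedback_fit")
}

#' @export
print.feedback_fit <- function(x, ...) {
  cat(sprintf("<feedback_fit> %s %s @ phi=%.2f: R2 = %.3f (n = %d)\n",
              x$model, x$direction, x$phi, x$r2, x$n))
  invisible(x)
}

# summed coefficient on the lateral body-position channels: the primary
# lateral gain (body markers share the lateral error, so collinear
# channels split it; the sum restores the physical gain)
lateral_gain <- function(fit) {
  g <- fit$gains[grep("_y_pos$", names(fit$gains))]
  sum(g)
}

# standard error of the summed lateral-position gain, from the fit's
# coefficient covariance
lateral_gain_se <- function(fit) {
  vc <- fit$vcov
  k <- grep("_y_pos$", rownames(vc))
  if (!length(k)) return(NA_real_)
  sqrt(sum(vc[k, k]))
}

#' Explained-variance phase profiles of both models
#'
#' Fits the body-state-error map and the foot-kinematics baseline at every
#' grid phase for every animal, then compares the two per-phase samples of
#' animal-level R-squared with a two-sample Kolmogorov-Smirnov test. The
#' swing-onset phase is the median stance-to-swing transition of the
#' placed foot.
#'
#' @param dev A `deviation_set`.
#' @param direction `"lateral"` or `"fore_aft"`.
#' @param leg Leg label (or vector pooled per animal).
#' @param min_animals Minimum animals for the KS comparison (default 5).
#' @return Object of class `model_comparison`: matrices `r2_body`,
#'   `r2_base` (animals x phases), per-phase `ks_p`/`ks_stat`,
#'   `swing_onset`, medians and IQRs, `gain_profile` (animals x phases
#'   lateral gain).
#' @export
r2_phase_profile <- function(dev, direction = c("lateral", "fore_aft"),
                             leg, min_animals = 5L) {
  direction <- match.arg(direction)
  animals <- unique(dev$meta$animal)
  M <- length(dev$phase)
  r2b <- r2f <- ab <- af <- gp <- matrix(NA_real_, length(animals), M,
                                         dimnames = list(animals, NULL))
  adj <- function(fit) {
    p <- length(fit$gains) - 1L - length(fit$dropped)
    1 - (1 - fit$r2) * (fit$n - 1) / max(fit$n - 1 - p, 1)
  }
  for (ai in seq_along(animals)) {
    rows <- which(dev$meta$animal == animals[ai] & dev$meta$leg %in% leg &
                    !dev$meta$extrapolated)
    if (length(rows) < 10L) next
    for (m in seq_len(M)) {
      fb <- fit_error_map(dev, dev$phase[m], direction, rows = rows)
      fs <- fit_baseline_map(dev, dev$phase[m], direction, rows = rows)
      r2b[ai, m] <- fb$r2; r2f[ai, m] <- fs$r2
      ab[ai, m] <- adj(fb); af[ai, m] <- adj(fs)
      gp[ai, m] <- lateral_gain(fb)
    }
  }
  ok <- stats::complete.cases(r2b)
  ks_p <- ks_stat <- rep(NA_real_, M)
  if (sum(ok) >= min_animals) {
    # the two models can have different predictor counts (body state
    # dimension vs the 4 foot channels); the distributional comparison
    # uses dimension-adjusted explained variance so in-sample optimism of
    # the larger model does not register as a feedback signature
    for (m in seq_len(M)) {
      if (all(ab[ok, m] == af[ok, m])) { ks_p[m] <- 1; ks_stat[m] <- 0; next }
      kt <- suppressWarnings(stats::ks.test(ab[ok, m], af[ok, m]))
      ks_p[m] <- kt$p.value; ks_stat[m] <- unname(kt$statistic)
    }
  } else {
    warning("fewer than ", min_animals, " animals: KS comparison skipped")
  }
  sw <- stats::median(dev$meta$phi_swing[dev$meta$leg %in% leg], na.rm = TRUE)
  structure(list(
    phase = dev$phase, direction = direction, leg = leg,
    r2_body = r2b, r2_base = r2f, gain_profile = gp,
    ks_p = ks_p, ks_stat = ks_stat, swing_onset = sw,
    median_body = apply(r2b, 2, stats::median, na.rm = TRUE),
    median_base = apply(r2f, 2, stats::median, na.rm = TRUE),
    iqr_body = apply(r2b, 2, stats::IQR, na.rm = TRUE),
    iqr_base = apply(r2f, 2, stats::IQR, na.rm = TRUE)),
    class = "model_comparison")
}

#' @export
print.model_comparison <- function(x, ...) {
  cat("<model_comparison>", x$direction, "/", paste(x$leg, collapse = "+"),
      ":", nrow(x$r2_body), "animals, swing onset at phi =",
      round(x$swing_onset, 2), "\n")
  cat("  max median R2 body:", round(max(x$median_body, na.rm = TRUE), 3),
      " baseline:", round(max(x$median_base, na.rm = TRUE), 3), "\n")
  invisible(x)
}

#' Control magnitude
#'
#' Per animal, the maximum over phases of the R-squared advantage of the
#' body-state model over the foot-kinematics baseline. Values near zero
#' indicate that body-state errors carry no information about placement
#' beyond the foot's own kinematics.
#'
#' @param comparison A `model_comparison`.
#' @return List: `per_animal` (named vector), `median`, `iqr`.
#' @export
control_magnitude <- function(comparison) {
  diffs <- comparison$r2_body - comparison$r2_base
  per <- apply(diffs, 1, function(z) if (all(is.na(z))) NA_real_
               else max(z, na.rm = TRUE))
  list(per_animal = per, median = stats::median(per, na.rm = TRUE),
       iqr = stats::IQR(per, na.rm = TRUE))
}

#' Direction-specific (medial/lateral) feedback gains
#'
#' Cycles are split by whether the lateral body-state error at `phi` is
#' directed away from (lateral) or toward (medial) the stance reference
#' foot (the opposite-group front limb used for spatial normalization);
#' the error map is fitted on each subset and the magnitude of the primary
#' lateral-position gain is returned per animal, with a paired Wilcoxon
#' signed-rank comparison and Cohen's d across animals.
#'
#' @param dev A `deviation_set`.
#' @param phi Evaluation phase (default: median swing onset).
#' @param leg Leg label(s).
#' @param min_n Minimum cycles per subset per animal (default
#'   `5 * (N + 1)`).
#' @return List: `per_animal` (data frame animal, gain_lateral,
#'   gain_medial), `test` (gateway record), `excluded`.
#' @export
directional_gains <- function(dev, phi = NULL, leg, min_n = NULL) {
  meta <- dev$meta
  phi <- phi %||% stats::median(meta$phi_swing[meta$leg %in% leg], na.rm = TRUE)
  m <- phase_index(dev$phase, phi)
  ypos <- grep("_y_pos$", dimnames(dev$dQ)[[3]])
  err_y <- rowMeans(dev$dQ[, m, ypos, drop = FALSE])
  N <- dim(dev$dQ)[3]
  min_n <- min_n %||% (5L * (N + 1L))
  out <- list(); excluded <- character(0)
  for (an in unique(meta$animal)) {
    rows <- which(meta$animal == an & meta$leg %in% leg & !meta$extrapolated)
    # lateral error: directed away from the stance reference foot's side
    lat <- rows[err_y[rows] * meta$ref_side[rows] < 0]
    med <- rows[err_y[rows] * meta$ref_side[rows] > 0]
    if (length(lat) < min_n || length(med) < min_n) {
      excluded <- c(excluded, an)
      next
    }
    gl <- lateral_gain(fit_error_map(dev, phi, "lateral", rows = lat))
    gm <- lateral_gain(fit_error_map(dev, phi, "lateral", rows = med))
    out[[length(out) + 1L]] <- data.frame(animal = an,
                                          gain_lateral = abs(gl),
                                          gain_medial = abs(gm),
                                          stringsAsFactors = FALSE)
  }
  per <- if (length(out)) do.call(rbind, out) else NULL
  test <- if (!is.null(per) && nrow(per) >= 3L)
    compare_groups(list(lateral = per$gain_lateral, medial = per$gain_medial),
                   paired = TRUE)
  else NULL
  list(per_animal = per, phi = dev$phase[m], test = test, excluded = excluded)
}
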