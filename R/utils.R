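`%||%` <- function(a, b) if (is.null(a)) b else a

# centered moving average; window forced odd, edges use shrinking windows
moving_average <- function(x, window) {
  window <- max(1L, as.integer(window))
  if (window %% 2L == 0L) window <- window + 1L
  if (window == 1L || length(x) < 3L) return(x)
  half <- (window - 1L) %/% 2L
  cs <- cumsum(c(0, x))
  n <- length(x)
  lo <- pmax(1L, seq_len(n) - half)
  hi <- pmin(n, seq_len(n) + half)
  (cs[hi + 1L] - cs[lo]) / (hi - lo + 1L)
}

# central-difference derivative on a possibly irregular time base
central_diff <- function(x, t) {
  n <- length(x)
  if (n < 2L) return(rep(NA_real_, n))
  d <- numeric(n)
  d[1L] <- (x[2L] - x[1L]) / (t[2L] - t[1L])
  d[n] <- (x[n] - x[n - 1L]) / (t[n] - t[n - 1L])
  if (n > 2L) {
    i <- 2L:(n - 1L)
    d[i] <- (x[i + 1L] - x[i - 1L]) / (t[i + 1L] - t[i - 1L])
  }
  d
}

# Local maxima with a prominence floor and a minimum spacing.
# Prominence of a peak: height above the higher of the two deepest valleys
# separating it from neighbouring higher terrain (standard definition,
# computed directly; series here are short enough for the O(n k) scan).
find_peaks <- function(x, min_prominence = 0, min_spacing = 1L) {
  n <- length(x)
  if (n < 3L) return(integer(0))
  i <- 2L:(n - 1L)
  cand <- i[x[i] > x[i - 1L] & x[i] >= x[i + 1L]]
  if (!length(cand)) return(integer(0))
  prom <- vapply(cand, function(p) {
    # walk left until a sample higher than x[p] (or the edge)
    lhs <- x[seq_len(p - 1L)]
    higher <- which(lhs > x[p])
    lmin <- min(lhs[seq.int(from = if (length(higher)) max(higher) else 1L,
                            to = p - 1L)])
    rhs <- x[seq.int(p + 1L, n)]
    higher <- which(rhs > x[p])
    rmin <- min(rhs[seq_len(if (length(higher)) min(higher) else length(rhs))])
    x[p] - max(lmin, rmin)
  }, numeric(1))
  keep <- cand[prom >= min_prominence]
  promk <- prom[prom >= min_prominence]
  if (!length(keep)) return(integer(0))
  # enforce spacing, keeping the most prominent peaks first
  ord <- order(promk, decreasing = TRUE)
  sel <- logical(length(keep))
  for (j in ord) {
    if (!any(sel & abs(keep - keep[j]) < min_spacing)) sel[j] <- TRUE
  }
  sort(keep[sel])
}

# OLS with intercept on a numeric predictor matrix. Columns with (near-)zero
# variance are dropped before fitting; if the design is still rank deficient
# a tiny ridge penalty is applied and the fit is flagged. Returns in-sample
# R^2 computed from residuals, as the closed-form normal-equations estimator
# would give.
ols_map <- function(X, y) {
  X <- as.matrix(X)
  keep <- apply(X, 2L, function(col) stats::var(col) > 1e-24 * (mean(col)^2 + 1))
  if (!any(keep)) {
    co <- rep(0, ncol(X))
    names(co) <- colnames(X)
    return(list(intercept = mean(y), coef = co, r2 = 0,
                dropped = colnames(X), ridged = FALSE, n = length(y)))
  }
  Xk <- X[, keep, drop = FALSE]
  Xc <- cbind(`(Intercept)` = 1, Xk)
  qrX <- qr(Xc)
  ridged <- FALSE
  XtXi <- NULL
  if (qrX$rank < ncol(Xc)) {
    ridged <- TRUE
    XtX <- crossprod(Xc)
    lam <- 1e-8 * mean(diag(XtX))
    XtXi <- solve(XtX + lam * diag(ncol(Xc)))
    beta <- drop(XtXi %*% crossprod(Xc, y))
  } else {
    beta <- qr.coef(qrX, y)
    XtXi <- chol2inv(qr.R(qrX))
  }
  fitted <- drop(Xc %*% beta)
  res <- y - fitted
  tss <- sum((y - mean(y))^2)
  r2 <- if (tss > 0) 1 - sum(res^2) / tss else NA_real_
  n <- length(y)
  sigma2 <- sum(res^2) / max(n - ncol(Xc), 1)
  vc <- sigma2 * XtXi
  dimnames(vc) <- list(colnames(Xc), colnames(Xc))
  co <- rep(0, ncol(X))
  names(co) <- colnames(X)
  co[keep] <- beta[-1L]
  se <- rep(NA_real_, ncol(X))
  names(se) <- colnames(X)
  se[keep] <- sqrt(diag(vc))[-1L]
  list(intercept = unname(beta[1L]), coef = co, r2 = r2, se = se,
       vcov = vc, dropped = colnames(X)[!keep], ridged = ridged, n = n,
       residuals = res)
}

# simple message logger used by processing steps; collects drop records
drop_log <- function() {
  env <- new.env(parent = emptyenv())
  env$records <- list()
  env
}

log_drop <- function(log, rule, detail) {
  if (is.null(log)) return(invisible(NULL))
  log$records[[length(log$records) + 1L]] <- list(rule = rule, detail = detail)
  invisible(NULL)
}
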