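#' Chatterjee's xi rank correlation with independence test
#'
#' Rank-based dependence coefficient sensitive to non-monotone
#' association. Pairs are sorted by `x` with a seeded random tie-break
#' among equal `x`; with `r_i` the number of `y_j <= y_i` and `l_i` the
#' number of `y_j >= y_i` (mid-count tie handling), the statistic is
#' `xi = 1 - n * sum(|r_(i+1) - r_i|) / (2 * sum(l_i * (n - l_i)))`,
#' which reduces to `1 - 3 * sum(|r_(i+1) - r_i|) / (n^2 - 1)` without
#' ties. Under independence (no ties) `sqrt(n) * xi` is asymptotically
#' Normal(0, 2/5); the test is right-tailed. `xi` is asymmetric in its
#' arguments by design and is not symmetrized.
#'
#' @param x,y Numeric vectors of equal length, n >= 5.
#' @param p_method `"asymptotic"` (default) or `"permutation"` (seeded,
#'   for small n or heavy ties).
#' @param n_perm Permutations for the permutation test (default 999).
#' @param tie_seed Seed for the random tie-break among equal `x` (and the
#'   permutation draw); fixed per call for reproducibility.
#' @return List of class `xi_result`: `xi`, `p`, `n`, `tie_handling`.
#' @export
chatterjee_xi <- function(x, y, p_method = c("asymptotic", "permutation"),
                          n_perm = 999L, tie_seed = 1L) {
  p_method <- match.arg(p_method)
  if (length(x) != length(y)) stop("x and y must have equal length")
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 5L) stop("need n >= 5")
  if (stats::var(y) == 0)
    return(structure(list(xi = 0, p = 1, n = n, tie_handling = "constant_y"),
                     class = "xi_result"))
  # local RNG so the seeded tie-break does not disturb the caller's stream
  old <- if (exists(".Random.seed", envir = globalenv()))
    get(".Random.seed", envir = globalenv()) else NULL
  on.exit(if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
          else if (exists(".Random.seed", envir = globalenv()))
            rm(".Random.seed", envir = globalenv()))
  set.seed(tie_seed)
  xi_stat <- function(xx, yy) {
    ord <- order(xx, stats::runif(n))
    ys <- yy[ord]
    r <- rank(ys, ties.method = "max")        # #{y_j <= y_i}
    l <- n + 1 - rank(ys, ties.method = "min") # #{y_j >= y_i}
    num <- n * sum(abs(diff(r)))
    den <- 2 * sum(l * (n - l))
    1 - num / den
  }
  xi <- xi_stat(x, y)
  ties <- anyDuplicated(y) > 0L
  if (p_method == "asymptotic") {
    p <- stats::pnorm(sqrt(n) * xi, mean = 0, sd = sqrt(2 / 5),
                      lower.tail = FALSE)
  } else {
    perm <- replicate(n_perm, xi_stat(x, sample(y)))
    p <- (1 + sum(perm >= xi)) / (n_perm + 1)
  }
  structure(list(xi = xi, p = p, n = n,
                 tie_handling = if (ties) "mid_count" else "none",
                 p_method = p_method),
            class = "xi_result")
}

#' @export
print.xi_result <- function(x, ...) {
  cat(sprintf("Chatterjee xi = %.4f, n = %d, p = %.4g (%s)\n",
              x$xi, x$n, x$p, x$p_method %||% "asymptotic"))
  invisible(x)
}

#' Cohen's d effect size
#'
#' Unpaired: difference of means over the pooled standard deviation.
#' Paired: mean of the differences over the standard deviation of the
#' differences.
#'
#' @param a,b Numeric vectors (equal length when `paired`).
#' @param paired Logical (default `FALSE`).
#' @return The effect size d.
#' @export
effect_size_d <- function(a, b, paired = FALSE) {
  if (length(a) < 2L || length(b) < 2L) stop("need n >= 2 per group")
  if (paired) {
    if (length(a) != length(b)) stop("paired groups must have equal length")
    dd <- a - b
    s <- stats::sd(dd)
    if (s == 0) stop("zero SD of differences")
    return(mean(dd) / s)
  }
  na <- length(a); nb <- length(b)
  sp <- sqrt(((na - 1) * stats::var(a) + (nb - 1) * stats::var(b)) /
               (na + nb - 2))
  if (sp == 0) stop("zero pooled SD")
  (mean(a) - mean(b)) / sp
}

#' Dunn's post hoc test
#'
#' All pairwise comparisons after a Kruskal-Wallis test, using rank-sum z
#' statistics with tie correction and (by default) false-discovery-rate
#' adjusted p-values.
#'
#' @param values Numeric vector.
#' @param groups Factor or character vector of group labels.
#' @param p_adjust Adjustment method for [stats::p.adjust()] (default
#'   `"BH"`).
#' @return Data frame: group1, group2, z, p, p_adj.
#' @export
dunn_test <- function(values, groups, p_adjust = "BH") {
  groups <- as.factor(groups)
  ok <- is.finite(values) & !is.na(groups)
  values <- values[ok]; groups <- droplevels(groups[ok])
  N <- length(values)
  r <- rank(values)
  ties <- table(values)
  tie_corr <- sum(ties^3 - ties) / (12 * (N - 1))
  rbar <- tapply(r, groups, mean)
  ns <- tapply(r, groups, length)
  gl <- levels(groups)
  pairs <- utils::combn(gl, 2)
  z <- p <- numeric(ncol(pairs))
  for (j in seq_len(ncol(pairs))) {
    g1 <- pairs[1, j]; g2 <- pairs[2, j]
    se <- sqrt((N * (N + 1) / 12 - tie_corr) * (1 / ns[g1] + 1 / ns[g2]))
    z[j] <- (rbar[g1] - rbar[g2]) / se
    p[j] <- 2 * stats::pnorm(-abs(z[j]))
  }
  data.frame(group1 = pairs[1, ], group2 = pairs[2, ], z = z, p = p,
             p_adj = stats::p.adjust(p, method = p_adjust),
             stringsAsFactors = FALSE)
}

#' Group comparison gateway
#'
#' Single entry point for the delegated standard tests: normality is
#' assessed per group with Shapiro-Wilk; if any group departs from
#' normality a nonparametric path is taken (Wilcoxon signed-rank or
#' rank-sum for two groups, Kruskal-Wallis with Dunn's post hoc and FDR
#' correction for more), otherwise t-test / one-way ANOVA. The record
#' logs the chosen test, statistic, p and (for two groups) Cohen's d.
#'
#' @param samples Named list of numeric vectors.
#' @param paired Logical, for two groups.
#' @param alpha Normality test level (default 0.05).
#' @return List: `test`, `statistic`, `p`, `d` (2 groups), `posthoc`
#'   (data frame, >2 groups), `normal`, `n`.
#' @export
compare_groups <- function(samples, paired = FALSE, alpha = 0.05) {
  stopifnot(is.list(samples), length(samples) >= 2)
  normal <- all(vapply(samples, function(s) {
    s <- s[is.finite(s)]
    if (length(s) < 3L || stats::sd(s) == 0) return(FALSE)
    stats::shapiro.test(s)$p.value >= alpha
  }, logical(1)))
  k <- length(samples)
  d <- if (k == 2L) effect_size_d(samples[[1]], samples[[2]], paired = paired)
       else NA_real_
  if (k == 2L) {
    ht <- if (normal)
      stats::t.test(samples[[1]], samples[[2]], paired = paired)
    else
      stats::wilcox.test(samples[[1]], samples[[2]], paired = paired,
                         exact = FALSE)
    return(list(test = ht$method, statistic = unname(ht$statistic),
                p = ht$p.value, d = d, normal = normal,
                n = vapply(samples, length, integer(1))))
  }
  values <- unlist(samples, use.names = FALSE)
  groups <- rep(names(samples) %||% as.character(seq_len(k)),
                vapply(samples, length, integer(1)))
  if (normal) {
    fit <- stats::aov(values ~ factor(groups))
    sm <- summary(fit)[[1]]
    list(test = "one-way ANOVA", statistic = sm$`F value`[1],
         p = sm$`Pr(>F)`[1], d = d, posthoc = NULL, normal = normal,
         n = vapply(samples, length, integer(1)))
  } else {
    kw <- stats::kruskal.test(values, factor(groups))
    list(test = "Kruskal-Wallis + Dunn (FDR)",
         statistic = unname(kw$statistic), p = kw$p.value, d = d,
         posthoc = dunn_test(values, groups), normal = normal,
         n = vapply(samples, length, integer(1)))
  }
}
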