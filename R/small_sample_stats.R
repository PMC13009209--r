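# Two-group inference for very small samples (the design of interest is
# n = 4 per group): small-sample-corrected Hedges' g, complete-enumeration
# randomisation tests, and stratified BCa bootstrap intervals.

as_two_group <- function(x, y) {
  x <- as.numeric(x); y <- as.numeric(y)
  if (length(x) < 2 || length(y) < 2)
    stop("degenerate-sample: each group needs at least 2 values")
  if (any(!is.finite(x)) || any(!is.finite(y)))
    stop("degenerate-sample: non-finite values")
  list(x = x, y = y)
}

#' Hedges' g (small-sample corrected standardized mean difference)
#'
#' `d = (mean(x) - mean(y)) / s_pooled` with the pooled SD on
#' `n1 + n2 - 2` degrees of freedom, multiplied by the correction
#' `J = 1 - 3 / (4 * (n1 + n2) - 9)`. Orientation: `x` is the epic group,
#' `y` the control group, so negative g means looser gating in epic
#' dreamers.
#'
#' @param x,y numeric vectors (epic, control), each of length >= 2.
#' @return Hedges' g, a real number.
#' @export
hedges_g <- function(x, y) {
  s <- as_two_group(x, y)
  n1 <- length(s$x); n2 <- length(s$y)
  sp2 <- ((n1 - 1) * stats::var(s$x) + (n2 - 1) * stats::var(s$y)) / (n1 + n2 - 2)
  if (sp2 <= 0) stop("degenerate-sample: pooled SD is zero")
  d <- (mean(s$x) - mean(s$y)) / sqrt(sp2)
  J <- 1 - 3 / (4 * (n1 + n2) - 9)
  J * d
}

#' Group mean difference (epic minus control)
#'
#' @param x,y numeric vectors (epic, control).
#' @return `mean(x) - mean(y)`.
#' @export
group_mean_difference <- function(x, y) {
  mean(as.numeric(x)) - mean(as.numeric(y))
}

#' Exact randomisation (permutation) test
#'
#' Enumerates every distinct assignment of the pooled values into groups of
#' the observed sizes — `choose(n1 + n2, n1)` assignments, 70 for the 4/4
#' design — and computes the two-sided p-value as the proportion of
#' assignments whose `|statistic|` is at least the observed `|statistic|`
#' (the observed assignment is included, so p >= 1 / n_permutations).
#' When the enumeration would exceed `cap`, set `monte_carlo = TRUE` to
#' sample random assignments instead.
#'
#' @param x,y numeric vectors (epic, control).
#' @param statistic function of `(x, y)` returning a scalar; default the
#'   mean difference.
#' @param alternative `"two.sided"` (default, by absolute value),
#'   `"less"` or `"greater"`.
#' @param cap maximum enumeration size before requiring Monte-Carlo mode.
#' @param monte_carlo sample `n_mc` random assignments instead of
#'   enumerating.
#' @param n_mc number of Monte-Carlo assignments.
#' @param seed integer seed for Monte-Carlo mode.
#' @return list of class `randomisation_test`: `p`, `observed`,
#'   `n_permutations`, `exact` (logical), `alternative`.
#' @export
exact_randomisation_test <- function(x, y,
                                     statistic = function(x, y) mean(x) - mean(y),
                                     alternative = c("two.sided", "less", "greater"),
                                     cap = 1e6, monte_carlo = FALSE,
                                     n_mc = 1e5, seed = NULL) {
  alternative <- match.arg(alternative)
  s <- as_two_group(x, y)
  n1 <- length(s$x); n2 <- length(s$y)
  pooled <- c(s$x, s$y)
  n_assign <- choose(n1 + n2, n1)
  obs <- statistic(s$x, s$y)

  stat_for <- function(idx) statistic(pooled[idx], pooled[-idx])
  if (!monte_carlo) {
    if (n_assign > cap)
      stop("enumeration of ", format(n_assign), " assignments exceeds cap; ",
           "rerun with monte_carlo = TRUE")
    combos <- utils::combn(n1 + n2, n1)
    stats_all <- apply(combos, 2, stat_for)
    n_perm <- ncol(combos)
  } else {
    if (!is.null(seed)) set.seed(seed)
    stats_all <- replicate(n_mc, stat_for(sample.int(n1 + n2, n1)))
    # the observed assignment is counted once, guaranteeing p > 0
    stats_all <- c(obs, stats_all)
    n_perm <- n_mc + 1
  }
  tol <- 1e-12 * max(1, abs(obs))
  p <- switch(alternative,
    two.sided = mean(abs(stats_all) >= abs(obs) - tol),
    less = mean(stats_all <= obs + tol),
    greater = mean(stats_all >= obs - tol))
  structure(list(p = p, observed = obs, n_permutations = n_perm,
                 exact = !monte_carlo, alternative = alternative),
            class = "randomisation_test")
}

#' Stratified BCa bootstrap confidence interval
#'
#' Groups are resampled independently with replacement (stratified
#' bootstrap). The bias-correction `z0` comes from the proportion of
#' bootstrap statistics below the observed value; the acceleration `a` from
#' grouped jackknife influence values (delete one subject at a time within
#' its own group); the interval endpoints are the bootstrap quantiles at the
#' BCa-adjusted percentiles.
#'
#' @param x,y numeric vectors (epic, control).
#' @param statistic function of `(x, y)` returning a scalar.
#' @param n_resamples number of bootstrap resamples; default 20000.
#' @param level confidence level; default 0.95.
#' @param seed integer seed (same seed, same interval).
#' @return list of class `bca_ci`: `lo`, `hi`, `estimate`, `level`,
#'   `n_resamples`, `z0`, `a`.
#' @export
bca_bootstrap_ci <- function(x, y,
                             statistic = function(x, y) mean(x) - mean(y),
                             n_resamples = 20000, level = 0.95, seed = NULL) {
  s <- as_two_group(x, y)
  if (!is.null(seed)) set.seed(seed)
  n1 <- length(s$x); n2 <- length(s$y)
  obs <- statistic(s$x, s$y)

  boot_stats <- numeric(n_resamples)
  for (b in seq_len(n_resamples)) {
    boot_stats[b] <- statistic(s$x[sample.int(n1, n1, replace = TRUE)],
                               s$y[sample.int(n2, n2, replace = TRUE)])
  }
  if (all(boot_stats == boot_stats[1])) {
    warning("degenerate bootstrap distribution; interval collapsed to a point")
    return(structure(list(lo = boot_stats[1], hi = boot_stats[1], estimate = obs,
                          level = level, n_resamples = n_resamples,
                          z0 = 0, a = 0), class = "bca_ci"))
  }
  # bias correction: proportion of bootstrap stats below the observed value
  prop <- mean(boot_stats < obs)
  prop <- min(max(prop, 1 / (n_resamples + 1)), n_resamples / (n_resamples + 1))
  z0 <- stats::qnorm(prop)
  # acceleration: grouped jackknife
  jack <- c(
    vapply(seq_len(n1), function(i) statistic(s$x[-i], s$y), numeric(1)),
    vapply(seq_len(n2), function(i) statistic(s$x, s$y[-i]), numeric(1))
  )
  infl <- mean(jack) - jack
  denom <- sum(infl^2)^1.5
  a <- if (denom == 0) 0 else sum(infl^3) / (6 * denom)

  zal <- stats::qnorm((1 - level) / 2)
  adj <- function(z) stats::pnorm(z0 + (z0 + z) / (1 - a * (z0 + z)))
  probs <- c(adj(zal), adj(-zal))
  qs <- unname(stats::quantile(boot_stats, probs, type = 7))
  structure(list(lo = qs[1], hi = qs[2], estimate = obs, level = level,
                 n_resamples = n_resamples, z0 = z0, a = a),
            class = "bca_ci")
}

#' Full two-group comparison report
#'
#' The inference stack applied to one metric: Hedges' g, the group mean
#' difference with its stratified BCa interval, and the exact randomisation
#' p-value (mean-difference statistic). No parametric test is reported;
#' at n = 4 per group the emphasis is descriptive magnitude and direction.
#'
#' @param x,y numeric vectors (epic, control).
#' @param n_resamples bootstrap resamples.
#' @param level confidence level.
#' @param seed integer seed.
#' @return list of class `group_comparison` with `hedges_g`,
#'   `mean_difference`, `ci_lo`, `ci_hi`, `p_perm`, `n_permutations`,
#'   `n_resamples`, `seed`.
#' @export
compare_groups <- function(x, y, n_resamples = 20000, level = 0.95, seed = 1L) {
  g <- hedges_g(x, y)
  md <- group_mean_difference(x, y)
  ci <- bca_bootstrap_ci(x, y, n_resamples = n_resamples, level = level,
                         seed = seed)
  rt <- exact_randomisation_test(x, y)
  structure(list(hedges_g = g, mean_difference = md,
                 ci_lo = ci$lo, ci_hi = ci$hi,
                 p_perm = rt$p, n_permutations = rt$n_permutations,
                 n_resamples = n_resamples, seed = seed),
            class = "group_comparison")
}
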