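test_that("sigmoid is the logistic function, stably evaluated", {
  expect_equal(sigmoid(0), 0.5)
  for (x in c(-3, -1, 1, 3))
    expect_equal(sigmoid(x), 0.5 * (1 + tanh(x / 2)), tolerance = 1e-14)
  set.seed(1)
  x <- rnorm(50, sd = 10)
  expect_equal(sigmoid(x) + sigmoid(-x), rep(1, 50), tolerance = 1e-14)
  expect_equal(sigmoid(700), 1)
  expect_equal(sigmoid(-700), 0)
  expect_false(any(is.nan(sigmoid(c(-700, 700)))))
})

test_that("misbinding probability sits exactly on 0.5 along the boundary", {
  expect_identical(misbinding_probability(0.7, 0.7, mobius_params(1, 1)), 0.5)
  set.seed(2)
  for (i in 1:20) {
    a <- runif(1, 0.1, 3); b <- runif(1, 0.1, 3); p <- runif(1, -2, 2)
    expect_identical(misbinding_probability(p, p, mobius_params(a, a)), 0.5)
    expect_equal(misbinding_probability(p, (a / b) * p, mobius_params(a, b)),
                 0.5, tolerance = 1e-12)
  }
  expect_equal(misbinding_probability(5, -4, mobius_params(0, 0)), 0.5)
  expect_equal(misbinding_probability(1.5, 0.5, mobius_params(2, 1)),
               0.9241, tolerance = 1e-4)
})

test_that("probability rises with plausibility and falls with gating", {
  set.seed(3)
  for (i in 1:20) {
    par <- mobius_params(runif(1, 0.1, 3), runif(1, 0.1, 3))
    p <- sort(rnorm(10)); g <- rnorm(1)
    expect_true(all(diff(misbinding_probability(p, g, par)) > 0))
    gg <- sort(rnorm(10))
    expect_true(all(diff(misbinding_probability(rnorm(1), gg, par)) < 0))
  }
})

test_that("the phase space is the pointwise model with an analytic boundary", {
  par <- mobius_params(1.3, 0.8)
  ps <- compute_phase_space(par, n_grid = 21)
  direct <- outer(ps$P_axis, ps$G_axis,
                  function(p, g) 1 / (1 + exp(-(1.3 * p - 0.8 * g))))
  expect_equal(ps$prob, direct, tolerance = 1e-12)
  # maximal vulnerability at the high-plausibility / low-gating corner
  expect_equal(which(ps$prob == max(ps$prob), arr.ind = TRUE)[1, ],
               c(row = 21L, col = 1L))
  expect_equal(ps$boundary$G, (1.3 / 0.8) * ps$boundary$P_S)
  # alpha = beta puts the boundary on the diagonal
  psd <- compute_phase_space(mobius_params(2, 2), n_grid = 11)
  expect_equal(psd$boundary$G, psd$boundary$P_S)
  expect_warning(psb <- compute_phase_space(mobius_params(1, 0), n_grid = 5),
                 "beta = 0")
  expect_null(psb$boundary)
})

test_that("simulated outcomes are calibrated to the model probabilities", {
  set.seed(4)
  y0 <- simulate_outcomes(rnorm(10000), rnorm(10000), mobius_params(0, 0))
  expect_lt(abs(mean(y0) - 0.5), 0.02)
  expect_true(all(simulate_outcomes(rep(1000, 50), rep(0, 50),
                                    mobius_params(1, 1)) == 1))
  # per-cell empirical rates within binomial error
  P <- rep(c(-1, 0, 1), each = 4000); G <- rep(c(-1, 1), times = 6000)
  par <- mobius_params(1.2, 0.7)
  y <- simulate_outcomes(P, G, par, seed = 9)
  for (p in c(-1, 0, 1)) for (g in c(-1, 1)) {
    sel <- P == p & G == g
    prob <- misbinding_probability(p, g, par)
    se <- sqrt(prob * (1 - prob) / sum(sel))
    expect_lt(abs(mean(y[sel]) - prob), 4 * se)
  }
})

test_that("IRLS recovers the generative weights and matches glm exactly", {
  set.seed(5)
  P <- rnorm(2000); G <- rnorm(2000)
  y <- simulate_outcomes(P, G, mobius_params(1.5, 2.0))
  f <- fit_misbinding_model(P, G, y)
  expect_true(f$converged)
  expect_lt(abs(f$alpha - 1.5), 0.15)
  expect_lt(abs(f$beta - 2.0), 0.15)
  # independent oracle: glm IRLS on the same design
  gm <- glm(y ~ 0 + P + offset_g, family = binomial,
            data = data.frame(y = y, P = P, offset_g = -G))
  expect_equal(f$alpha, unname(coef(gm)[1]), tolerance = 1e-6)
  expect_equal(f$beta, unname(coef(gm)[2]), tolerance = 1e-6)
  se <- sqrt(diag(vcov(gm)))
  expect_equal(c(f$se_alpha, f$se_beta), unname(se), tolerance = 1e-4)
})

test_that("the fitted likelihood dominates the truth and the score vanishes", {
  set.seed(6)
  P <- rnorm(500); G <- rnorm(500)
  par <- mobius_params(1, 1.5)
  y <- simulate_outcomes(P, G, par)
  f <- fit_misbinding_model(P, G, y)
  ll <- function(a, b) {
    eta <- a * P - b * G
    sum(y * eta - log1p(exp(eta)))
  }
  expect_gte(f$loglik + 1e-8, ll(1, 1.5))
  expect_equal(f$loglik, ll(f$alpha, f$beta), tolerance = 1e-8)
  mu <- misbinding_probability(P, G, mobius_params(f$alpha, f$beta))
  expect_lt(max(abs(c(sum((y - mu) * P), sum((y - mu) * -G)))), 1e-6)
})

test_that("pathological designs raise the named errors", {
  set.seed(7)
  P <- rnorm(100); G <- rnorm(100)
  expect_error(fit_misbinding_model(P, G, rep(1, 100)), "class")
  expect_error(fit_misbinding_model(P[1:5], G[1:5], c(0, 1, 0, 1, 0)),
               "insufficient-data")
  expect_error(fit_misbinding_model(P, 2 * P, simulate_outcomes(P, 2 * P,
               mobius_params(1, 1), seed = 1)), "collinear")
  # perfectly separated outcomes
  ysep <- as.integer(P - G > 0)
  expect_error(fit_misbinding_model(P, G, ysep), "separation")
})

test_that("alpha and beta are identified only relative to predictor scale", {
  set.seed(8)
  P <- rnorm(300); G <- rnorm(300)
  par <- mobius_params(1.2, 0.9)
  p1 <- misbinding_probability(P, G, par)
  p2 <- misbinding_probability(3 * P, G, mobius_params(1.2 / 3, 0.9))
  expect_equal(p1, p2, tolerance = 1e-12)
})

test_that("the plausibility scorer standardizes bounded sub-scores", {
  set.seed(9)
  co <- runif(30); gd <- runif(30); tc <- runif(30)
  s <- plausibility_score(co, gd, tc)
  expect_equal(mean(s), 0, tolerance = 1e-12)
  expect_equal(sd(s), 1, tolerance = 1e-12)
  expect_equal(order(s), order(rowMeans(cbind(co, gd, tc))))
  expect_error(plausibility_score(1.2, 0.5, 0.5), "domain")
})
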