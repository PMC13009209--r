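test_that("logit is the clipped log-odds", {
  expect_equal(logit(0.5), 0)
  expect_equal(logit(0.73), 0.9946, tolerance = 1e-4)
  expect_equal(logit(1, eps = 1e-6), log((1 - 1e-6) / 1e-6))
  expect_equal(logit(1, eps = 1e-6), 13.8155, tolerance = 1e-4)
  expect_true(is.finite(logit(0)))
  p <- seq(0.01, 0.99, by = 0.01)
  expect_true(all(diff(logit(p)) > 0))  # monotone
  expect_error(logit(1.2), "domain")
  expect_error(logit(0.5, eps = 0.5), "domain")
})

test_that("the control reference rejects degenerate controls", {
  f <- demo_cohort(seed = 1)
  f2 <- f[f$group == "control", ][c(1, 1), ]
  expect_error(fit_control_reference(f2), "degenerate-reference")
  expect_error(fit_control_reference(f[1, , drop = FALSE]), "insufficient-data")
})

test_that("controls z-scored against their own reference standardize exactly", {
  f <- demo_cohort(seed = 2)
  ref <- fit_control_reference(f)
  Z <- control_zscore(f[f$group == "control", ], ref)
  expect_equal(unname(colMeans(Z)), c(0, 0, 0), tolerance = 1e-12)
  expect_equal(unname(apply(Z, 2, sd)), c(1, 1, 1), tolerance = 1e-12)
})

test_that("reference means converge to the generative parameters", {
  big <- generate_cohort_features(cohort_config(
    n_control = 10000, n_epic = 2,
    effect_sizes = c(coupling = 0, rem_bout = 0, steepness = 0), seed = 3))
  ref <- fit_control_reference(big)
  se <- ref$sigma / sqrt(ref$n_control)
  gen <- c(logit(0.40), 5.0, 2.0)
  expect_true(all(abs(ref$mu - gen) < 2 * se + 1e-8))
})

test_that("z-scoring centres and scales on the transformed feature scale", {
  f <- demo_cohort(seed = 4)
  ref <- fit_control_reference(f)
  at_mu <- data.frame(subject_id = "s", group = "epic", channel = "C3-C4",
                      coupling_vl = plogis(ref$mu[1]),
                      rem_mean_bout_min = ref$mu[2],
                      one_over_f_steepness = ref$mu[3])
  expect_equal(unname(control_zscore(at_mu, ref)[1, ]), c(0, 0, 0),
               tolerance = 1e-9)
  below <- data.frame(subject_id = "s", group = "epic", channel = "C3-C4",
                      coupling_vl = plogis(ref$mu[1] - ref$sigma[1]),
                      rem_mean_bout_min = ref$mu[2] - ref$sigma[2],
                      one_over_f_steepness = ref$mu[3] - ref$sigma[3])
  expect_equal(unname(control_zscore(below, ref)[1, ]), c(-1, -1, -1),
               tolerance = 1e-9)
})

test_that("missing features propagate as missing, never zero", {
  f <- demo_cohort(seed = 5)
  ref <- fit_control_reference(f)
  f$coupling_vl[6] <- NA
  expect_warning(Z <- control_zscore(f, ref), "missing")
  expect_true(all(is.na(Z[6, ])))
  expect_true(is.na(rgi_min(Z[6, ])))
  expect_true(is.na(signed_distance_to_control(Z, ref)[6]))
})

test_that("RGI_min is the permutation-symmetric weakest link", {
  expect_equal(rgi_min(c(0, 0, 0)), 0)
  expect_equal(rgi_min(c(-1.2, 0.3, 0.8)), -1.2)
  set.seed(6)
  for (i in 1:20) {
    z <- rnorm(3)
    expect_equal(rgi_min(z), rgi_min(sample(z)))
    expect_lte(rgi_min(z), mean(z))
    # decreasing any component never increases the minimum
    j <- sample(3, 1); z2 <- z; z2[j] <- z2[j] - runif(1, 0, 2)
    expect_lte(rgi_min(z2), rgi_min(z))
  }
})

test_that("shrinkage keeps every eigenvalue at or above lambda", {
  set.seed(7)
  for (i in 1:20) {
    A <- matrix(rnorm(9), 3)
    Sigma <- crossprod(A)
    lam <- runif(1, 0.05, 0.5)
    ev <- eigen(shrink_covariance(Sigma, lam), symmetric = TRUE,
                only.values = TRUE)$values
    expect_true(all(ev >= lam - 1e-10))
  }
})

test_that("signed distance matches an explicit 3x3 inversion oracle", {
  Sigma <- matrix(0.5, 3, 3); diag(Sigma) <- 1
  ref <- structure(list(mu = c(0, 0, 0), sigma = c(1, 1, 1), Sigma = Sigma,
                        lambda = 0.20, eps = 1e-6, n_control = 4),
                   class = "control_reference")
  z <- c(-1, -1, -1)
  Sl <- 0.8 * Sigma + 0.2 * diag(3)
  oracle <- -sqrt(drop(t(z) %*% inv3(Sl) %*% z))
  expect_equal(signed_distance_to_control(z, ref), oracle, tolerance = 1e-12)
  expect_equal(signed_distance_to_control(c(0, 0, 0), ref), 0)
  # identity covariance at any lambda stays the identity
  ref$Sigma <- diag(3)
  expect_equal(signed_distance_to_control(z, ref), -sqrt(3), tolerance = 1e-12)
})

test_that("distance magnitude is exchangeable when Sigma is exchangeable", {
  Sigma <- matrix(0.4, 3, 3); diag(Sigma) <- 1
  ref <- structure(list(mu = c(0, 0, 0), sigma = c(1, 1, 1), Sigma = Sigma,
                        lambda = 0.20, eps = 1e-6, n_control = 4),
                   class = "control_reference")
  set.seed(8)
  for (i in 1:10) {
    z <- rnorm(3)
    d <- abs(signed_distance_to_control(z, ref))
    dp <- abs(signed_distance_to_control(sample(z), ref))
    expect_equal(dp, d, tolerance = 1e-12)
  }
})

test_that("oriented cohort effects push epic RGI below control RGI", {
  f <- demo_cohort(seed = 9, effect = 1, n = 30)
  r <- compute_rgi(f)
  expect_lt(mean(r$rgi_min[r$group == "epic"]),
            mean(r$rgi_min[r$group == "control"]))
  expect_lt(mean(r$signed_distance[r$group == "epic"]),
            mean(r$signed_distance[r$group == "control"]))
})

test_that("compute_rgi keeps epic rows out of the reference", {
  f <- demo_cohort(seed = 10, effect = 3)
  ref <- attr(compute_rgi(f), "reference")
  ref_ctrl <- fit_control_reference(f[f$group == "control", ])
  expect_equal(ref$mu, ref_ctrl$mu)
  expect_equal(ref$Sigma, ref_ctrl$Sigma)
})
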