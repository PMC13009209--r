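test_that("SO phase advances at the oscillation frequency", {
  fs <- 128; t <- (0:(fs * 60 - 1)) / fs
  ep <- make_epoch(cos(2 * pi * 0.75 * t), fs)
  ph <- so_phase_series(ep)
  mid <- 2000:4000
  slope <- mean(diff(ph[mid]) %% (2 * pi)) * fs
  expect_equal(slope, 2 * pi * 0.75, tolerance = 1e-3)
  # phase 0 at the positive peak
  pk <- which.max(ep$samples[mid]) + mid[1] - 1
  expect_lt(abs(ph[pk]), 0.1)
})

test_that("a +pi/2 input shift appears as a uniform phase offset", {
  fs <- 128; t <- (0:(fs * 60 - 1)) / fs
  ph0 <- so_phase_series(make_epoch(cos(2 * pi * 0.75 * t), fs))
  ph1 <- so_phase_series(make_epoch(cos(2 * pi * 0.75 * t + pi / 2), fs))
  d <- wrap_phase(ph1 - ph0)[1000:6000]
  expect_equal(mean(d), pi / 2, tolerance = 0.01)
  expect_lt(sd(d), 0.01)
})

test_that("estimated SO phase tracks the generator's phase at snr 5", {
  tr <- coupling_truth(kappa = 2, aperiodic_exponent = 1)
  ep <- synthesize_coupled_epoch(tr, duration_s = 300, fs = 128, snr = 5,
                                 seed = 21)
  fs <- ep$fs
  t <- (seq_along(ep$samples) - 1) / fs
  true_phase <- wrap_phase(2 * pi * tr$so_freq * t)
  est <- so_phase_series(ep)
  sel <- seq(fs * 5, length(t) - fs * 5)  # avoid filter edge effects
  expect_gt(circ_corr(est[sel], true_phase[sel]), 0.9)
})

test_that("phase series refuses epochs shorter than 10 SO cycles", {
  ep <- make_epoch(rnorm(128 * 20), 128)
  expect_error(so_phase_series(ep), "insufficient-data")
})

test_that("a silent epoch yields zero spindle events", {
  ep <- make_epoch(numeric(128 * 60), 128)
  expect_equal(nrow(detect_spindle_events(ep)), 0)
})

test_that("a single injected burst is found at its true location", {
  set.seed(4)
  fs <- 128; n <- fs * 60; t <- (0:(n - 1)) / fs
  x <- 0.05 * rnorm(n)
  centre <- 15
  idx <- abs(t - centre) <= 0.5
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, sum(idx) - 1) / (sum(idx) - 1))
  x[idx] <- x[idx] + win * cos(2 * pi * 13 * (t[idx] - centre))
  ev <- detect_spindle_events(make_epoch(x, fs))
  expect_equal(nrow(ev), 1)
  expect_lt(abs(ev$peak_time - centre), 0.2)
})

test_that("detection recall against injected bursts is at least 0.8", {
  tr <- coupling_truth(kappa = 2, aperiodic_exponent = 2)
  ep <- synthesize_coupled_epoch(tr, duration_s = 300, fs = 128, snr = 5,
                                 seed = 31)
  truth_times <- attr(ep, "burst_times")
  expect_gt(length(truth_times), 50)
  ev <- detect_spindle_events(ep)
  hits <- sum(vapply(truth_times,
                     function(b) any(abs(ev$peak_time - b) < 0.25), logical(1)))
  expect_gte(hits / length(truth_times), 0.8)
})

test_that("vector length follows the circular-statistics contracts", {
  # perfect concentration
  r <- coupling_vector_length(rep(pi / 4, 7))
  expect_equal(r$R, 1)
  expect_equal(r$preferred_phase, pi / 4)
  # antipodal cancellation
  expect_lt(coupling_vector_length(c(0, pi))$R, 1e-12)
  # Bessel-ratio oracle at kappa = 1
  set.seed(12)
  expect_lt(abs(coupling_vector_length(rvonmises(10000, 0, 1))$R - 0.446), 0.02)
  # rotation invariance of R; preferred phase co-rotates
  set.seed(13)
  ph <- rvonmises(200, 0.5, 2)
  r0 <- coupling_vector_length(ph)
  r1 <- coupling_vector_length(wrap_phase(ph + 1.1))
  expect_equal(r1$R, r0$R, tolerance = 1e-12)
  expect_equal(wrap_phase(r1$preferred_phase - r0$preferred_phase), 1.1,
               tolerance = 1e-9)
  # duplication idempotence
  for (n in c(2, 5, 20))
    expect_equal(coupling_vector_length(rep(0.3, n))$R, 1)
  expect_error(coupling_vector_length(numeric(0)), "insufficient-data")
  expect_true(coupling_vector_length(rnorm(50))$R <= 1)
})

test_that("aperiodic steepness recovers the generative exponent", {
  set.seed(6)
  fs <- 256; n <- fs * 300
  ep0 <- make_epoch(rnorm(n), fs)
  expect_lt(abs(aperiodic_steepness(ep0)), 0.15)        # white noise
  ep2 <- make_epoch(remgate:::colored_noise(n, fs, 2), fs)
  expect_lt(abs(aperiodic_steepness(ep2) - 2), 0.2)
})

test_that("steepness is amplitude-free", {
  set.seed(7)
  ep <- make_epoch(remgate:::colored_noise(256 * 120, 256, 1), 256)
  ep7 <- make_epoch(7 * ep$samples, 256)
  expect_equal(aperiodic_steepness(ep7), aperiodic_steepness(ep),
               tolerance = 1e-10)
})

test_that("steepness demands enough bins and duration", {
  ep <- make_epoch(rnorm(256 * 30), 256)
  expect_error(aperiodic_steepness(ep), "insufficient-data")
  ep2 <- make_epoch(rnorm(256 * 120), 256)
  expect_error(aperiodic_steepness(ep2, fit_band = c(44.8, 45)),
               "insufficient-data")
  expect_error(aperiodic_steepness(ep2, fit_band = c(40, 200)), "invalid-config")
})

test_that("REM mean bout duration is plain arithmetic with a missing sentinel", {
  h <- data.frame(stage = c("N2", "REM", "W", "REM"),
                  onset_s = c(0, 600, 900, 1000),
                  duration_s = c(600, 300, 100, 900))
  expect_equal(rem_mean_bout_duration(h), 10)
  h2 <- data.frame(stage = "N2", onset_s = 0, duration_s = 600)
  expect_warning(v <- rem_mean_bout_duration(h2), "missing")
  expect_true(is.na(v))
})

test_that("end-to-end extraction recovers the generative (R, chi) pair", {
  tr <- coupling_truth(kappa = 2, aperiodic_exponent = 1.5)
  ep <- synthesize_coupled_epoch(tr, duration_s = 600, fs = 128, snr = 5,
                                 seed = 41)
  ev <- detect_spindle_events(ep)
  expect_lt(abs(coupling_vector_length(ev)$R - von_mises_R(2)), 0.05)
  expect_lt(abs(aperiodic_steepness(ep) - 1.5), 0.2)
})
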