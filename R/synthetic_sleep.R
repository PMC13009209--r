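STAGES <- c("W", "N1", "N2", "N3", "REM")

#' Ground-truth parameters for a coupled epoch
#'
#' Describes the generative state of one synthetic EEG-like epoch: the
#' slow-oscillation (SO) frequency, the spindle band, the von Mises law of
#' spindle-burst occurrence phase relative to the SO, and the aperiodic
#' (1/f) background exponent.
#'
#' @param kappa von Mises concentration of burst phases, >= 0 (0 = uniform).
#' @param preferred_phase mean burst phase in radians; 0 is the SO positive
#'   peak (the package phase convention).
#' @param so_freq SO frequency, Hz.
#' @param spindle_band numeric length-2, spindle band (lo, hi) in Hz.
#' @param aperiodic_exponent background exponent chi >= 0; PSD ~ f^-chi.
#' @return an object of class `coupling_truth`.
#' @export
coupling_truth <- function(kappa = 2, preferred_phase = 0, so_freq = 0.75,
                           spindle_band = c(11, 16), aperiodic_exponent = 2) {
  if (!is.numeric(kappa) || kappa < 0) stop("invalid-config: kappa must be >= 0")
  if (aperiodic_exponent < 0) stop("invalid-config: aperiodic_exponent must be >= 0")
  if (length(spindle_band) != 2 || spindle_band[1] >= spindle_band[2])
    stop("invalid-config: spindle_band must be (lo, hi) with lo < hi")
  if (so_freq <= 0 || so_freq >= spindle_band[1])
    stop("invalid-config: so_freq must be positive and below the spindle band")
  structure(list(kappa = kappa,
                 preferred_phase = wrap_phase(preferred_phase),
                 so_freq = so_freq,
                 spindle_band = as.numeric(spindle_band),
                 aperiodic_exponent = aperiodic_exponent),
            class = "coupling_truth")
}

#' Generate a synthetic hypnogram
#'
#' Bout durations are exponential with per-stage means; the stage sequence is
#' a Markov chain with the given transition weights. Adjacent bouts of the
#' same stage are merged, so a chain confined to one stage yields a single
#' bout spanning the night.
#'
#' @param stage_mean_bouts named numeric, mean bout duration in seconds for
#'   each of `W, N1, N2, N3, REM` (stages may be omitted; they are then
#'   unreachable).
#' @param transition_weights square matrix with matching dimnames; row i is
#'   proportional to the transition probabilities out of stage i. Defaults to
#'   a generic adult-night pattern.
#' @param total_s total recording length in seconds.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @param initial_stage starting stage; default the first stage with positive
#'   weight out of `W`, or the first named stage.
#' @return a `hypnogram`: data.frame with columns `stage`, `onset_s`,
#'   `duration_s`, contiguous from 0 to `total_s`.
#' @export
generate_hypnogram <- function(stage_mean_bouts = c(W = 300, N1 = 120, N2 = 900,
                                                    N3 = 600, REM = 300),
                               transition_weights = NULL,
                               total_s = 8 * 3600, seed = NULL,
                               initial_stage = NULL) {
  if (total_s <= 0) stop("invalid-config: total_s must be > 0")
  if (any(!is.finite(stage_mean_bouts)) || any(stage_mean_bouts <= 0))
    stop("invalid-config: all stage mean bout durations must be > 0")
  stages <- names(stage_mean_bouts)
  if (is.null(stages) || !all(stages %in% STAGES))
    stop("invalid-config: stage_mean_bouts must be named with stages among W, N1, N2, N3, REM")
  if (is.null(transition_weights)) {
    transition_weights <- default_transition_weights()[stages, stages, drop = FALSE]
  }
  tw <- as.matrix(transition_weights)
  if (is.null(rownames(tw)) || !setequal(rownames(tw), stages))
    stop("invalid-config: transition_weights dimnames must match stage names")
  tw <- tw[stages, stages, drop = FALSE]
  if (any(tw < 0)) stop("invalid-config: transition weights must be >= 0")
  if (any(rowSums(tw) <= 0)) stop("invalid-config: every stage needs an outgoing weight")
  if (!is.null(seed)) set.seed(seed)

  cur <- if (!is.null(initial_stage)) initial_stage else stages[1]
  stopifnot(cur %in% stages)
  st <- character(0); dur <- numeric(0)
  elapsed <- 0
  while (elapsed < total_s) {
    d <- stats::rexp(1, rate = 1 / stage_mean_bouts[[cur]])
    d <- min(d, total_s - elapsed)
    st <- c(st, cur); dur <- c(dur, d)
    elapsed <- elapsed + d
    p <- tw[cur, ]
    cur <- sample(stages, 1, prob = p)
  }
  # merge consecutive identical stages into single bouts
  runs <- rle(st)
  dur <- as.numeric(tapply(dur, rep(seq_along(runs$lengths), runs$lengths), sum))
  st <- runs$values
  h <- data.frame(stage = st,
                  onset_s = cumsum(c(0, dur[-length(dur)])),
                  duration_s = dur,
                  stringsAsFactors = FALSE)
  class(h) <- c("hypnogram", "data.frame")
  h
}

default_transition_weights <- function() {
  m <- matrix(0, 5, 5, dimnames = list(STAGES, STAGES))
  m["W", ]   <- c(0, 8, 2, 0, 0)
  m["N1", ]  <- c(2, 0, 8, 0, 1)
  m["N2", ]  <- c(1, 2, 0, 5, 3)
  m["N3", ]  <- c(1, 0, 8, 0, 2)
  m["REM", ] <- c(3, 3, 4, 0, 0)
  m
}

#' Synthesize an epoch with known SO-spindle coupling and 1/f background
#'
#' The signal is a slow oscillation (cosine, phase 0 at positive peak) plus
#' Hann-windowed spindle-band bursts, one per SO cycle with probability
#' `burst_prob`, whose peak phase relative to the SO is von Mises
#' (`truth$preferred_phase`, `truth$kappa`), plus background noise with
#' power spectral density proportional to `f^-chi`.
#'
#' @param truth a [coupling_truth()] object.
#' @param duration_s epoch length, seconds (>= 30).
#' @param fs sampling rate, Hz; must be at least 4x the spindle-band upper
#'   edge.
#' @param snr ratio of SO component SD to noise SD; `Inf` disables noise.
#' @param burst_prob probability that an SO cycle carries a burst.
#' @param burst_dur_s burst (Hann packet) duration, seconds.
#' @param burst_amp burst amplitude relative to the unit-amplitude SO.
#' @param channel,stage metadata labels.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return an `epoch_signal` (list with `samples`, `fs`, `channel`, `stage`)
#'   carrying attributes `burst_times` and `burst_phases` (ground truth) and
#'   `truth`.
#' @export
synthesize_coupled_epoch <- function(truth, duration_s = 300, fs = 256,
                                     snr = 5, burst_prob = 0.5,
                                     burst_dur_s = 1, burst_amp = 0.5,
                                     channel = "C3-C4", stage = "REM",
                                     seed = NULL) {
  stopifnot(inherits(truth, "coupling_truth"))
  if (duration_s < 30) stop("invalid-config: duration_s must be >= 30 s")
  if (fs < 4 * truth$spindle_band[2])
    stop("invalid-config: fs below 4x the spindle-band upper edge (Nyquist margin)")
  if (!is.null(seed)) set.seed(seed)

  n <- round(duration_s * fs)
  t <- (seq_len(n) - 1) / fs
  f0 <- truth$so_freq
  so <- cos(2 * pi * f0 * t)

  n_cycles <- floor(duration_s * f0)
  has_burst <- stats::runif(n_cycles) < burst_prob
  k <- which(has_burst) - 1L
  phases <- rvonmises(length(k), truth$preferred_phase, truth$kappa)
  times <- (k + phases / (2 * pi)) / f0
  keep <- times >= burst_dur_s / 2 & times <= duration_s - burst_dur_s / 2
  times <- times[keep]; phases <- phases[keep]

  x <- so
  fc <- mean(truth$spindle_band)
  half <- round(burst_dur_s * fs / 2)
  win_len <- 2L * half + 1L
  win <- 0.5 - 0.5 * cos(2 * pi * seq(0, win_len - 1) / (win_len - 1))
  for (i in seq_along(times)) {
    c0 <- round(times[i] * fs) + 1L
    idx <- (c0 - half):(c0 + half)
    ok <- idx >= 1L & idx <= n
    carrier <- cos(2 * pi * fc * (t[idx[ok]] - times[i]))
    x[idx[ok]] <- x[idx[ok]] + burst_amp * win[ok] * carrier
  }
  if (is.finite(snr)) {
    if (snr <= 0) stop("invalid-config: snr must be > 0")
    noise <- colored_noise(n, fs, truth$aperiodic_exponent) * stats::sd(so) / snr
    x <- x + noise
  }
  ep <- structure(list(samples = x, fs = fs, channel = channel, stage = stage),
                  class = "epoch_signal")
  attr(ep, "burst_times") <- times
  attr(ep, "burst_phases") <- phases
  attr(ep, "truth") <- truth
  ep
}

#' Cohort generator configuration
#'
#' Control rows are drawn from Gaussians (coupling on the logit scale, then
#' inverse-transformed so values stay in (0,1)); epic rows are shifted down
#' by `effect_sizes * feature_sds` on each oriented feature, so a positive
#' effect size means looser gating in the epic group on that feature.
#'
#' @param n_control,n_epic group sizes, >= 2.
#' @param effect_sizes named numeric (`coupling`, `rem_bout`, `steepness`):
#'   standardized control-minus-epic shifts in control-SD units.
#' @param feature_means control means: coupling vector length in (0,1), REM
#'   mean bout duration in minutes, 1/f steepness (= -aperiodic slope).
#' @param feature_sds control SDs; the coupling SD applies on the logit scale.
#' @param channel channel label attached to every row.
#' @param seed integer seed (mandatory for reproducibility).
#' @return an object of class `cohort_config`.
#' @export
cohort_config <- function(n_control = 4, n_epic = 4,
                          effect_sizes = c(coupling = 1, rem_bout = 1, steepness = 1),
                          feature_means = c(coupling = 0.40, rem_bout = 5.0, steepness = 2.0),
                          feature_sds = c(coupling = 0.35, rem_bout = 1.2, steepness = 0.30),
                          channel = "C3-C4", seed = 1L) {
  need <- c("coupling", "rem_bout", "steepness")
  stopifnot(all(need %in% names(effect_sizes)),
            all(need %in% names(feature_means)),
            all(need %in% names(feature_sds)))
  if (n_control < 2 || n_epic < 2) stop("invalid-config: group sizes must be >= 2")
  if (any(feature_sds[need] <= 0)) stop("invalid-config: feature SDs must be > 0")
  if (feature_means[["coupling"]] <= 0 || feature_means[["coupling"]] >= 1)
    stop("invalid-config: coupling mean must lie in (0,1)")
  if (is.null(seed)) stop("invalid-config: seed is mandatory")
  structure(list(n_control = as.integer(n_control), n_epic = as.integer(n_epic),
                 effect_sizes = effect_sizes[need],
                 feature_means = feature_means[need],
                 feature_sds = feature_sds[need],
                 channel = channel, seed = as.integer(seed)),
            class = "cohort_config")
}

#' Generate a two-group cohort feature table
#'
#' @param config a [cohort_config()].
#' @return data.frame of class `gating_features` with columns `subject_id`,
#'   `group` (control/epic), `channel`, `coupling_vl`, `rem_mean_bout_min`,
#'   `one_over_f_steepness`. Reproducible given the config seed.
#' @export
generate_cohort_features <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  set.seed(config$seed)
  m <- config$feature_means; s <- config$feature_sds; es <- config$effect_sizes
  nC <- config$n_control; nE <- config$n_epic

  mu_logit <- logit(m[["coupling"]])
  cpl <- c(stats::rnorm(nC, mu_logit, s[["coupling"]]),
           stats::rnorm(nE, mu_logit - es[["coupling"]] * s[["coupling"]], s[["coupling"]]))
  cpl <- stats::plogis(cpl)
  eps <- 1e-6
  if (any(cpl <= eps | cpl >= 1 - eps)) {
    warning("coupling values clipped into (eps, 1-eps) after back-transform")
    cpl <- pmin(pmax(cpl, eps), 1 - eps)
  }
  bout <- c(stats::rnorm(nC, m[["rem_bout"]], s[["rem_bout"]]),
            stats::rnorm(nE, m[["rem_bout"]] - es[["rem_bout"]] * s[["rem_bout"]], s[["rem_bout"]]))
  if (any(bout <= 0)) {
    warning("non-positive REM bout durations truncated to 0.05 min")
    bout <- pmax(bout, 0.05)
  }
  steep <- c(stats::rnorm(nC, m[["steepness"]], s[["steepness"]]),
             stats::rnorm(nE, m[["steepness"]] - es[["steepness"]] * s[["steepness"]], s[["steepness"]]))

  out <- data.frame(
    subject_id = c(sprintf("ctrl%02d", seq_len(nC)), sprintf("epic%02d", seq_len(nE))),
    group = c(rep("control", nC), rep("epic", nE)),
    channel = config$channel,
    coupling_vl = cpl,
    rem_mean_bout_min = bout,
    one_over_f_steepness = steep,
    stringsAsFactors = FALSE
  )
  class(out) <- c("gating_features", "data.frame")
  out
}
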