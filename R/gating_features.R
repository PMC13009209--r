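#' Instantaneous slow-oscillation phase
#'
#' Band-passes the epoch to the SO band (zero-phase frequency-domain filter)
#' and returns the instantaneous phase of the analytic signal. Phase
#' convention: 0 radians at the positive peak of the filtered SO, increasing
#' through +pi/2 on the falling flank (phases wrapped to (-pi, pi]).
#'
#' @param epoch an `epoch_signal`.
#' @param so_band SO band (lo, hi) in Hz; default 0.3-1.5 Hz.
#' @return numeric vector, one phase per sample, radians in (-pi, pi].
#' @export
so_phase_series <- function(epoch, so_band = c(0.3, 1.5)) {
  stopifnot(inherits(epoch, "epoch_signal"))
  n <- length(epoch$samples)
  if (n / epoch$fs < 10 / so_band[1])
    stop("insufficient-data: epoch shorter than 10 SO cycles at the band lower edge")
  filt <- fft_bandpass(epoch$samples, epoch$fs, so_band[1], so_band[2])
  wrap_phase(Arg(analytic_signal(filt)))
}

#' Detect spindle events and their SO phase
#'
#' Band-passes to the spindle band, takes the analytic-signal envelope,
#' smooths it (0.2 s moving average), and marks events wherever the envelope
#' exceeds `mean + threshold_sd * SD` for at least `min_dur_s`. One event per
#' supra-threshold run, located at the envelope peak, with the SO phase at
#' that sample attached.
#'
#' @param epoch an `epoch_signal`.
#' @param spindle_band spindle band (lo, hi), Hz.
#' @param threshold_sd envelope threshold in SD units above the mean.
#' @param min_dur_s minimum supra-threshold duration, seconds.
#' @param so_band SO band passed to [so_phase_series()].
#' @return data.frame of class `spindle_events`: `peak_time` (s),
#'   `so_phase_at_peak` (rad, (-pi, pi]), `amplitude` (envelope units),
#'   time-ordered; zero rows when nothing crosses threshold.
#' @export
detect_spindle_events <- function(epoch, spindle_band = c(11, 16),
                                  threshold_sd = 1.5, min_dur_s = 0.3,
                                  so_band = c(0.3, 1.5)) {
  stopifnot(inherits(epoch, "epoch_signal"))
  fs <- epoch$fs
  if (fs < 4 * spindle_band[2])
    stop("invalid-config: fs below 4x the spindle-band upper edge")
  x <- epoch$samples
  empty <- data.frame(peak_time = numeric(0), so_phase_at_peak = numeric(0),
                      amplitude = numeric(0))
  class(empty) <- c("spindle_events", "data.frame")
  if (stats::sd(x) == 0) return(empty)

  filt <- fft_bandpass(x, fs, spindle_band[1], spindle_band[2])
  env <- Mod(analytic_signal(filt))
  k <- max(1L, round(0.2 * fs))
  env <- stats::filter(env, rep(1 / k, k), sides = 2)
  env[is.na(env)] <- 0
  env <- as.numeric(env)

  thr <- mean(env) + threshold_sd * stats::sd(env)
  above <- env > thr
  if (!any(above)) return(empty)
  r <- rle(above)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1L
  keep <- r$values & (r$lengths >= min_dur_s * fs)
  if (!any(keep)) return(empty)
  starts <- starts[keep]; ends <- ends[keep]

  peak_idx <- mapply(function(a, b) a + which.max(env[a:b]) - 1L, starts, ends)
  phase <- so_phase_series(epoch, so_band)
  ev <- data.frame(peak_time = (peak_idx - 1) / fs,
                   so_phase_at_peak = phase[peak_idx],
                   amplitude = env[peak_idx])
  ev <- ev[order(ev$peak_time), , drop = FALSE]
  rownames(ev) <- NULL
  class(ev) <- c("spindle_events", "data.frame")
  ev
}

#' SO-spindle coupling vector length
#'
#' Mean resultant vector of the unit phasors at event phases: its modulus
#' `R` in `[0, 1]` is the coupling vector length, its argument the preferred
#' phase. `R` is invariant to a global phase rotation.
#'
#' @param events a `spindle_events` data.frame, or a numeric vector of
#'   phases in radians.
#' @return list with elements `R` and `preferred_phase` (radians, (-pi, pi]).
#' @export
coupling_vector_length <- function(events) {
  phases <- if (is.data.frame(events)) events$so_phase_at_peak else events
  if (length(phases) < 1)
    stop("insufficient-data: at least one spindle event is required")
  z <- mean(exp(1i * phases))
  list(R = min(Mod(z), 1), preferred_phase = wrap_phase(Arg(z)))
}

#' Aperiodic 1/f steepness
#'
#' Welch PSD followed by ordinary least squares of `log10(power)` on
#' `log10(frequency)` over `fit_band`; returns the negated slope, so larger
#' values mean a steeper spectral decay (lower cortical excitability). The
#' value is invariant to any positive rescaling of the signal
#' (amplitude-free contract).
#'
#' @param epoch an `epoch_signal`, at least 60 s long.
#' @param fit_band fit band (lo, hi), Hz; default 20-45 Hz, above the
#'   oscillatory peaks so a plain log-log fit is appropriate.
#' @return steepness (= -slope), a real number.
#' @export
aperiodic_steepness <- function(epoch, fit_band = c(20, 45)) {
  stopifnot(inherits(epoch, "epoch_signal"))
  if (length(epoch$samples) / epoch$fs < 60)
    stop("insufficient-data: epoch must be at least 60 s for the aperiodic fit")
  if (fit_band[1] <= 0 || fit_band[2] >= epoch$fs / 2 || fit_band[1] >= fit_band[2])
    stop("invalid-config: fit_band must lie within (0, fs/2)")
  psd <- welch_psd(epoch$samples, epoch$fs)
  sel <- psd$freq >= fit_band[1] & psd$freq <= fit_band[2] & psd$power > 0
  if (sum(sel) < 5)
    stop("insufficient-data: fewer than 5 PSD bins in the fit band")
  fit <- stats::lm.fit(cbind(1, log10(psd$freq[sel])), log10(psd$power[sel]))
  -unname(fit$coefficients[2])
}

#' Mean REM bout duration
#'
#' @param h a `hypnogram`.
#' @return arithmetic mean of REM bout durations in minutes; `NA` with a
#'   warning when the hypnogram contains no REM bout (missing, never zero).
#' @export
rem_mean_bout_duration <- function(h) {
  stopifnot(is.data.frame(h), all(c("stage", "duration_s") %in% names(h)))
  d <- h$duration_s[h$stage == "REM"]
  if (length(d) == 0) {
    warning("no REM bouts in hypnogram; REM mean bout duration is missing")
    return(NA_real_)
  }
  mean(d) / 60
}

#' Extract the three oriented gating features for one subject
#'
#' Convenience wrapper: coupling vector length from detected spindle events,
#' REM mean bout duration from the hypnogram, 1/f steepness from the epoch.
#' All three are oriented so that larger values mean tighter gating. When a
#' feature cannot be computed (no spindle events, no REM) it is returned as
#' `NA`, never imputed.
#'
#' @param epoch an `epoch_signal`.
#' @param hypnogram a `hypnogram`.
#' @param subject_id,group identifiers copied into the output row.
#' @param spindle_band,so_band,fit_band,threshold_sd extraction settings.
#' @return one-row `gating_features` data.frame.
#' @export
extract_gating_features <- function(epoch, hypnogram, subject_id, group,
                                    spindle_band = c(11, 16),
                                    so_band = c(0.3, 1.5),
                                    fit_band = c(20, 45),
                                    threshold_sd = 1.5) {
  ev <- detect_spindle_events(epoch, spindle_band, threshold_sd, so_band = so_band)
  vl <- if (nrow(ev) >= 1) coupling_vector_length(ev)$R else {
    warning("no spindle events detected; coupling feature missing")
    NA_real_
  }
  bout <- suppressWarnings(rem_mean_bout_duration(hypnogram))
  steep <- aperiodic_steepness(epoch, fit_band)
  out <- data.frame(subject_id = subject_id, group = group,
                    channel = epoch$channel,
                    coupling_vl = vl, rem_mean_bout_min = bout,
                    one_over_f_steepness = steep,
                    stringsAsFactors = FALSE)
  class(out) <- c("gating_features", "data.frame")
  out
}
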