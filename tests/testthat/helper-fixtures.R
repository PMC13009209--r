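# Shared fixtures: epochs built in code, plus small independent oracles.

make_epoch <- function(samples, fs, channel = "C3-C4", stage = "REM") {
  structure(list(samples = samples, fs = fs, channel = channel, stage = stage),
            class = "epoch_signal")
}

# Fisher-Lee circular-circular correlation.
circ_corr <- function(a, b) {
  A <- Arg(mean(exp(1i * a)))
  B <- Arg(mean(exp(1i * b)))
  sum(sin(a - A) * sin(b - B)) /
    sqrt(sum(sin(a - A)^2) * sum(sin(b - B)^2))
}

# Explicit 3x3 matrix inverse through the adjugate (independent of solve()).
inv3 <- function(M) {
  co <- matrix(0, 3, 3)
  for (i in 1:3) for (j in 1:3)
    co[i, j] <- (-1)^(i + j) * det(M[-i, -j, drop = FALSE])
  t(co) / det(M)
}

# A small two-group cohort with a known oriented separation.
demo_cohort <- function(seed = 1, effect = 1, n = 4) {
  generate_cohort_features(cohort_config(
    n_control = n, n_epic = n,
    effect_sizes = c(coupling = effect, rem_bout = effect, steepness = effect),
    seed = seed))
}
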