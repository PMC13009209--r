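---
title: "Methods: REM gating integrity and the misbinding model"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: REM gating integrity and the misbinding model}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(remgate)
```

## The scientific problem

Most dreams are forgotten. A clinically distinct minority — "epic" dreams:
continuous, often mundane, recalled all night long with autobiographical
confidence — behave instead like memories. One systems-level reading is
that REM sleep normally *gates* its own simulations: the physiology of the
state (neuromodulatory tone, hippocampal novelty control, oscillatory
organisation) prevents internally generated sequences from being encoded,
and epic dreaming marks a failure of that gate.

`remgate` implements the quantitative scaffolding of that account in two
coupled parts:

1. an **empirical pipeline** that reduces sleep physiology to a scalar REM
   Gating Integrity (RGI) per subject and compares small groups of epic
   dreamers and controls, and
2. a **probabilistic model** of the gate itself,
   $P(M=\mathrm{veridical}\mid S) = \sigma(\alpha\,\mathcal{P}(S) -
   \beta\,G(\theta,\gamma))$ with $\sigma(x) = 1/(1+e^{-x})$,
   where $\mathcal{P}(S)$ scores the structural plausibility of a dream
   sequence and $G$ the gating integrity.

Because clinical polysomnography in this area sits behind governance
restrictions, the package is built around a synthetic-data module with
known ground truth; everything downstream is validated by parameter
recovery rather than by access to a particular cohort.

## Synthetic data: what is emulated, and what is not

The generators emulate exactly the statistical structure the pipeline
consumes, nothing more.

* **Hypnograms.** Stage sequences are a Markov chain over
  {W, N1, N2, N3, REM} with exponential bout durations. The exponential
  choice makes the *mean bout duration* — the feature the pipeline uses —
  a sufficient statistic of the generator. Bouts are continuous-time
  (no 30-s epoch grid); adjacent same-stage bouts are merged.
* **Coupled epochs.** A unit cosine slow oscillation (SO, default
  0.75 Hz), spindle-band Hann packets (default 11–16 Hz centre, 1 s, one
  per SO cycle with probability 0.5) whose occurrence phase relative to
  the SO is von Mises$(\mu,\kappa)$, and background noise with PSD
  $\propto f^{-\chi}$ obtained by spectral shaping of white noise. The
  signal-to-noise ratio is the SD ratio of the SO component to the noise
  (default 5). Defaults: fs = 256 Hz, 300-s epochs.
* **Cohorts.** Per-subject features are Gaussian around control means
  (coupling drawn on the logit scale and inverse-transformed, so the
  pipeline's logit transform is exactly variance-stabilising under the
  generative model), with the epic group shifted down by
  `effect_size × SD` on every oriented feature. Defaults are 4 vs 4
  subjects and 1-SD shifts — a two-group cohort at the scale and
  separation the pipeline is designed for. Control means (coupling 0.40,
  REM bout 5 min, steepness 2.0) are ordinary values for adult sleep EEG.

What the generator does **not** emulate: artifacts, stage-dependent
spectra, spindle morphology, within-night nonstationarity, or any
dependence between the three features beyond what sampling induces.
Passing tests therefore demonstrate that the pipeline recovers its own
generative parameters — a necessary condition — not that it would behave
identically on clinical recordings.

## Feature extraction

* **SO phase** comes from the analytic signal (FFT Hilbert construction)
  of the band-passed epoch. Filtering is a zero-phase frequency-domain
  band-pass (FFT bins outside the band zeroed), chosen over an IIR design
  because SO bands sit at ~0.002 of the sampling rate, where recursive
  filters are numerically fragile; the whole epoch is in memory anyway.
  Phase convention: 0 at the SO positive peak. Only phase *differences*
  matter downstream, but the convention is fixed and tested.
* **Spindle events**: band-pass, analytic-signal envelope, 0.2-s moving
  average, threshold `mean + 1.5·SD` of the envelope, minimum 0.3 s above
  threshold, one event per supra-threshold run at its envelope peak. The
  1.5-SD default matters: at the generator's burst density a large
  fraction of the record is spindle activity, which inflates the envelope
  SD; a 2-SD cut leaves supra-threshold runs shorter than 0.3 s and
  detection collapses. 1.5 SD is within the range used by standard
  amplitude-threshold spindle detectors and gives recall ≥ 0.95 against
  injected bursts at snr 5.
* **Coupling** is the mean resultant vector length of event phases —
  the population value for von Mises phases is the Bessel ratio
  $I_1(\kappa)/I_0(\kappa)$, which the tests use as an oracle.
* **1/f steepness** is −slope of an ordinary least-squares fit of
  $\log_{10}$ power on $\log_{10}$ frequency over a Welch PSD
  (Hann windows, 4-s segments, 50 % overlap). The default fit band is
  **20–45 Hz**. Two considerations fix it: the band must sit above the
  spindle band so a plain (peak-free) log–log fit is unbiased, and it must
  span enough log-frequency to pin the slope — over 30–45 Hz the
  single-epoch slope SD is ≈ 0.12, too coarse to resolve exponent
  differences of interest, while 20–45 Hz halves it (≈ 0.07) at no cost in
  peak contamination. A peak-aware spectral parameterisation is
  deliberately out of scope; the band is config-exposed.
* **REM continuity** is the arithmetic mean REM bout duration in minutes.
  A hypnogram with no REM yields a missing value with a warning — missing
  features propagate as missing rows throughout, never as zeros.

## The RGI composites

With control-group means $\mu$ and SDs $s$ (computed with the $n-1$
denominator; coupling on the logit scale, clip bound $10^{-6}$), each
subject gets $z_i = (x_i - \mu_i)/s_i$, oriented so larger = tighter
gating. Two scalar composites follow:

* **RGI$_{\min}$** $= \min(z_1, z_2, z_3)$. The subscript is read as the
  weakest-link minimum: a gate is only as tight as its loosest mechanism.
  This is an implementation decision (a plausible alternative would be a
  mean); it is monotone in every component and never exceeds any of them.
* **Signed distance-to-control**
  $= \mathrm{sign}(\bar z)\,\sqrt{z^\top \Sigma_\lambda^{-1} z}$ with
  $\Sigma_\lambda = (1-\lambda)\Sigma + \lambda I$, $\lambda = 0.20$
  fixed. $\Sigma$ is the covariance of the *z-scored* controls (so the
  distance is a correlation-shrunk Mahalanobis distance); shrinkage
  guarantees every eigenvalue of $\Sigma_\lambda$ is at least $\lambda$,
  hence invertibility even with 4 controls. The sign convention (sign of
  the mean z; ties resolved positive, which a continuous cohort never
  hits) makes "negative = net looser gating" explicit; the magnitude
  alone is sign-blind.

The reference is always fit on controls only, and is serialised to JSON so
any RGI table can be reproduced exactly from its reference file.

## Small-sample inference

At 4 subjects per group, parametric tests carry little information, so the
stack is:

* **Hedges' g**: pooled-SD standardized mean difference (epic − control)
  with the correction $J = 1 - 3/(4N-9)$; for $N=8$, $J = 1 - 3/23$.
* **Exact randomisation test**: all $\binom{8}{4} = 70$ assignments of the
  pooled values to groups, two-sided by $|$statistic$|$, observed
  assignment counted — so $p \ge 1/70$ and the smallest attainable
  two-sided p is $2/70 \approx 0.0286$. Larger designs above the
  enumeration cap switch to seeded Monte-Carlo sampling with the observed
  assignment included for validity.
* **Stratified BCa bootstrap** (default 20,000 resamples): groups
  resampled independently; bias correction $z_0$ from the fraction of
  bootstrap statistics below the observed value; acceleration $a$ from
  grouped jackknife influence values (delete one subject within its own
  group, matching the stratified resampling); endpoints by
  quantile interpolation at the adjusted percentiles. With $z_0=a=0$ the
  interval reduces to the percentile interval, which the tests assert.

The coverage of the BCa interval is checked by simulation at a design
where its second-order asymptotics apply: 300 replicates of two Gaussian
samples of 40 per group (true mean difference 1), 2,000 resamples each,
requiring empirical coverage in $95 \pm 4$ %. At n = 4 BCa intervals are
reported descriptively, exactly as the permutation p accompanies rather
than replaces the effect size.

## The misbinding model

The model is a two-parameter, **no-intercept** logistic: the printed
equation has no constant term, which pins $P = 0.5$ at the origin of the
standardized $(\mathcal{P}, G)$ plane and makes the decision boundary the
exact line $\beta G = \alpha \mathcal{P}$. Consequences and choices:

* `sigmoid()` is evaluated branchlessly via
  $e^{-\log(1+e^{-|x|})}$ and its reflection, exact to the last ulp over
  $|x| \le 700$. On the boundary the linear predictor is exactly 0
  whenever $\alpha\mathcal{P}$ and $\beta G$ are equal as floating-point
  numbers, and the returned probability is then exactly 0.5.
* Estimation is in-house IRLS (Newton scoring) on the design
  $(\mathcal{P}, -G)$, converged at $|\Delta\ell| < 10^{-10}$ or 100
  iterations, SEs from the inverse observed information. The estimator is
  part of the package's validated surface; `glm()` serves as an
  independent oracle in the tests (agreement to $10^{-6}$), never as the
  implementation. Perfect separation and single-class outcomes raise
  named errors.
* $\alpha, \beta$ are identified only relative to the predictor scales
  (multiplying $\mathcal{P}$ by $c$ and dividing $\alpha$ by $c$ changes
  nothing); predictors are therefore standardized by convention, and the
  `plausibility_score()` helper (mean of bounded sub-scores, then
  z-standardized) is explicitly a placeholder — no empirical
  operationalisation of $\mathcal{P}(S)$ exists yet.
* `G` defaults to RGI$_{\min}$ under an identity map; the linkage is
  config-exposed because the gating term summarises more physiology than
  the three-feature composite measures.

Parameter recovery under the model's own sampling (100 replicates at
n = 2,000, $\alpha = 1.5$, $\beta = 2$) achieves bias < 0.05 and
RMSE < 0.15 on both weights.

## Pipeline, seeds, problem sizes

`run_pipeline()` chains simulate → extract → RGI → stats → phase space
from one validated config (unknown keys rejected; `seed` mandatory;
$\lambda$ defaults to 0.20; resamples ≥ 1,000). One top-level seed is
split once into per-stage child seeds via `set.seed(seed)` followed by a
single `sample.int(2^31 - 1, ...)` draw, so identical configs give
byte-identical outputs; channels differ only by seed stream, mirroring a
primary-channel / sensitivity-channel design rather than modelling
channel physiology.

Test and demonstration problem sizes were chosen to pin each quantity to
its stated tolerance: 10,000 von Mises draws for the Bessel-ratio oracle
(±0.02), 300-s epochs for 1/f recovery (±0.2), 200 nights for the
exponential bout mean (±10 %), 100 × 2,000 observations for parameter
recovery, 300 × 2,000 resamples for BCa coverage, 50 four-versus-four
cohorts for the direction check.

## Known limitations

* The generator's independence assumptions make the control covariance
  $\Sigma$ near-diagonal; the shrinkage distance is exercised, but its
  behaviour under strong feature correlation is covered only by
  constructed-matrix tests.
* The weakest-link definition of RGI$_{\min}$ and the sign rule of the
  distance are documented package decisions, not settled field
  conventions.
* Signal-level cohort simulation realises target features as one epoch and
  one night per subject; extraction noise (especially the handful of REM
  bouts per night) is substantial at that size, which is faithful to how
  noisy such features are in practice but means feature-level and
  signal-level cohorts are not interchangeable for power analyses.
* The misbinding model cannot be fit to real dream-outcome data yet — no
  labelled outcomes exist; all fitting claims are recovery claims under
  the model's own sampling.
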