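# The MOBIUS misbinding model: a no-intercept logistic model
#   P(M = veridical | S) = sigmoid(alpha * P_S - beta * G)
# where P_S is the structural plausibility of a REM-generated sequence and
# G the REM gating integrity (both on standardized scales; larger G =
# tighter gating). alpha and beta weight the two composites; with no
# intercept the model pins P = 0.5 at alpha * P_S = beta * G, the decision
# boundary between discarded simulation and memory-candidate content.

#' Numerically stable logistic sigmoid
#'
#' `sigmoid(x) = 1 / (1 + exp(-x))`, computed branchlessly via
#' `exp(-log1p(exp(-|x|)))` so it neither overflows nor loses precision for
#' |x| up to several hundred.
#'
#' @param x numeric vector.
#' @return values in `[0, 1]`; `sigmoid(x) + sigmoid(-x) == 1`.
#' @export
sigmoid <- function(x) {
  stopifnot(is.numeric(x))
  # log(sigmoid(x)) = -log1p(exp(-x)) for x >= 0; reflect for x < 0
  pos <- exp(-log1p(exp(-abs(x))))
  ifelse(x >= 0, pos, 1 - pos)
}

#' MOBIUS parameters
#'
#' @param alpha weight on structural plausibility, expected >= 0.
#' @param beta weight on gating integrity, expected >= 0.
#' @return object of class `mobius_params`. Negative weights are allowed
#'   but draw a warning: they invert the model's interpretation.
#' @export
mobius_params <- function(alpha = 1, beta = 1) {
  stopifnot(is.finite(alpha), is.finite(beta))
  if (alpha < 0 || beta < 0)
    warning("negative alpha or beta inverts the interpretability contract")
  structure(list(alpha = alpha, beta = beta), class = "mobius_params")
}

#' Misbinding probability
#'
#' `P(M = veridical | S) = sigmoid(alpha * P_S - beta * G)`: strictly
#' increasing in structural plausibility `P_S` and strictly decreasing in
#' gating integrity `G` whenever alpha, beta > 0. Returns exactly 0.5 on
#' the decision boundary `alpha * P_S == beta * G`.
#'
#' @param P_S structural plausibility score(s), standardized scale.
#' @param G gating integrity score(s), standardized scale.
#' @param par a [mobius_params()] object (or list with `alpha`, `beta`).
#' @return probability vector in `[0, 1]`.
#' @export
misbinding_probability <- function(P_S, G, par = mobius_params()) {
  stopifnot(is.numeric(P_S), is.numeric(G))
  sigmoid(par$alpha * P_S - par$beta * G)
}

#' Phase space of the misbinding model
#'
#' Evaluates the misbinding probability on a (P_S, G) grid and returns the
#' analytic P = 0.5 decision boundary, the line `G = (alpha / beta) * P_S`.
#' The high-plausibility / low-gating corner of the grid carries the
#' maximal probability (maximal vulnerability to misbinding).
#'
#' @param par a [mobius_params()] object.
#' @param P_range,G_range axis ranges, standardized scale.
#' @param n_grid grid points per axis, >= 2.
#' @return list of class `phase_space`: `P_axis`, `G_axis`, `prob`
#'   (matrix, rows index `P_axis`, columns `G_axis`), and `boundary`
#'   (data.frame `P_S`, `G`, or `NULL` with a warning when `beta == 0`
#'   leaves no finite boundary).
#' @export
compute_phase_space <- function(par = mobius_params(), P_range = c(-3, 3),
                                G_range = c(-3, 3), n_grid = 101) {
  stopifnot(n_grid >= 2, length(P_range) == 2, length(G_range) == 2)
  P_axis <- seq(P_range[1], P_range[2], length.out = n_grid)
  G_axis <- seq(G_range[1], G_range[2], length.out = n_grid)
  prob <- outer(P_axis, G_axis,
                function(p, g) misbinding_probability(p, g, par))
  boundary <- if (par$beta == 0) {
    warning("beta = 0: the P = 0.5 boundary is not a finite line in G")
    NULL
  } else {
    data.frame(P_S = P_axis, G = (par$alpha / par$beta) * P_axis)
  }
  structure(list(P_axis = P_axis, G_axis = G_axis, prob = prob,
                 boundary = boundary, par = par),
            class = "phase_space")
}

#' Simulate binary misbinding outcomes
#'
#' Independent Bernoulli draws at the model probabilities; the generative
#' counterpart of [fit_misbinding_model()] used for parameter-recovery
#' studies.
#'
#' @param P_S,G predictor vectors (recycled to common length).
#' @param par a [mobius_params()] object.
#' @param seed integer seed; `NULL` uses the current RNG state.
#' @return integer vector of 0/1 outcomes.
#' @export
simulate_outcomes <- function(P_S, G, par = mobius_params(), seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  p <- misbinding_probability(P_S, G, par)
  as.integer(stats::runif(length(p)) < p)
}

#' Maximum-likelihood fit of the misbinding model
#'
#' Fits the no-intercept two-parameter logistic by iteratively reweighted
#' least squares (Newton scoring) on the design `(P_S, -G)`, so the
#' coefficients are alpha and beta directly. Converged when the
#' log-likelihood improves by less than `tol` (default 1e-10) or after
#' `max_iter` iterations. Standard errors come from the inverse observed
#' information at the optimum.
#'
#' @param P_S,G predictor vectors.
#' @param outcomes 0/1 outcomes.
#' @param max_iter maximum Newton iterations.
#' @param tol log-likelihood convergence tolerance.
#' @return list of class `mobius_fit`: `alpha`, `beta`, `se_alpha`,
#'   `se_beta`, `loglik`, `n`, `converged`, `iterations`.
#' @export
fit_misbinding_model <- function(P_S, G, outcomes, max_iter = 100, tol = 1e-10) {
  y <- as.numeric(outcomes)
  stopifnot(length(P_S) == length(y), length(G) == length(y),
            all(y %in% c(0, 1)))
  n <- length(y)
  if (n < 10) stop("insufficient-data: at least 10 observations required")
  if (length(unique(y)) < 2)
    stop("degenerate-sample: both outcome classes must be present")
  X <- cbind(P_S = P_S, neg_G = -G)
  if (abs(stats::cor(X[, 1], X[, 2])) > 1 - 1e-10)
    stop("degenerate-sample: P_S and G are collinear")

  beta <- c(0, 0)
  # log-likelihood: sum( y*eta - log(1 + exp(eta)) ), computed stably
  loglik <- function(b) {
    eta <- drop(X %*% b)
    sum(y * eta - (pmax(eta, 0) + log1p(exp(-abs(eta)))))
  }
  ll_old <- loglik(beta)
  converged <- FALSE
  it <- 0
  for (it in seq_len(max_iter)) {
    eta <- drop(X %*% beta)
    mu <- sigmoid(eta)
    w <- mu * (1 - mu)
    # perfect separation: the linear predictor runs away while classifying
    # every observation correctly
    if (max(abs(eta)) > 30 &&
        all(y[eta > 0] == 1) && all(y[eta < 0] == 0) && all(w < 1e-10)) {
      stop("non-convergence: perfect separation between outcome classes")
    }
    XtW <- t(X * w)
    H <- XtW %*% X
    score <- drop(t(X) %*% (y - mu))
    step <- tryCatch(solve(H, score), error = function(e)
      stop("non-convergence: singular information matrix (possible perfect separation)"))
    beta <- beta + step
    ll_new <- loglik(beta)
    if (abs(ll_new - ll_old) < tol) { converged <- TRUE; ll_old <- ll_new; break }
    ll_old <- ll_new
  }
  if (!converged && max(abs(drop(X %*% beta))) > 30)
    stop("non-convergence: perfect separation between outcome classes")
  mu <- sigmoid(drop(X %*% beta))
  H <- t(X * (mu * (1 - mu))) %*% X
  se <- sqrt(diag(solve(H)))
  structure(list(alpha = unname(beta[1]), beta = unname(beta[2]),
                 se_alpha = unname(se[1]), se_beta = unname(se[2]),
                 loglik = ll_old, n = n, converged = converged,
                 iterations = it),
            class = "mobius_fit")
}

#' Placeholder structural-plausibility scorer
#'
#' Maps bounded sub-scores of a dream sequence (narrative coherence,
#' goal-directedness, temporal continuity, each in `[0, 1]`) to their mean
#' and then z-standardizes across sequences. The model itself only requires
#' a scalar standardized `P_S`; how plausibility is operationalized from
#' dream reports is an open empirical question, and this scorer is an
#' explicitly provisional convenience.
#'
#' @param coherence,goal_directedness,temporal_continuity numeric vectors
#'   in `[0, 1]`, one value per sequence.
#' @return standardized plausibility scores (mean 0, SD 1 across input
#'   sequences).
#' @export
plausibility_score <- function(coherence, goal_directedness, temporal_continuity) {
  sub <- cbind(coherence, goal_directedness, temporal_continuity)
  if (any(sub < 0 | sub > 1)) stop("domain error: sub-scores must lie in [0, 1]")
  raw <- rowMeans(sub)
  if (stats::sd(raw) == 0)
    stop("degenerate-sample: all sequences share one plausibility score")
  as.numeric(scale(raw))
}
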