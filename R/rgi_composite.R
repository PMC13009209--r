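# REM Gating Integrity composites. The three features (logit coupling, REM
# mean bout duration, 1/f steepness) are z-scored against the control group
# only; RGI_min is the weakest-link minimum of the three z's, and the signed
# distance-to-control is a shrinkage-covariance Mahalanobis distance with the
# sign of the mean z (negative = net looser gating).

FEATURE_COLS <- c("coupling_vl", "rem_mean_bout_min", "one_over_f_steepness")

#' Logit with clipping
#'
#' `log(p / (1 - p))` after clipping `p` into `[eps, 1 - eps]`, so the
#' closed endpoints 0 and 1 map to large finite values. Used to
#' variance-stabilize the coupling vector length before control z-scoring.
#'
#' @param p value(s) in `[0, 1]`.
#' @param eps clip bound in `(0, 0.01]`; default 1e-6.
#' @return real value(s); monotone increasing in `p`.
#' @export
logit <- function(p, eps = 1e-6) {
  if (any(!is.na(p) & (p < 0 | p > 1))) stop("domain error: p must lie in [0, 1]")
  if (eps <= 0 || eps > 0.01) stop("domain error: eps must lie in (0, 0.01]")
  p <- pmin(pmax(p, eps), 1 - eps)
  log(p / (1 - p))
}

#' Fit the control reference for RGI scoring
#'
#' Means and SDs (n-1 denominator) of the control rows on the transformed
#' feature scale (coupling logit-transformed first), plus the covariance of
#' the control z-vectors and the shrinkage weight lambda. Epic rows never
#' enter the reference.
#'
#' @param features a `gating_features` data.frame; rows with
#'   `group == "control"` are used (a table with no `group` column is taken
#'   to be all controls).
#' @param lambda shrinkage weight in `[0, 1]` for
#'   `Sigma_lambda = (1 - lambda) * Sigma + lambda * I`; default 0.20.
#' @param eps logit clip bound.
#' @return object of class `control_reference`: `mu`, `sigma` (3-vectors,
#'   order: logit coupling, REM bout min, steepness), `Sigma` (3x3, on the z
#'   scale), `lambda`, `n_control`.
#' @export
fit_control_reference <- function(features, lambda = 0.20, eps = 1e-6) {
  stopifnot(is.data.frame(features), all(FEATURE_COLS %in% names(features)))
  if (lambda < 0 || lambda > 1) stop("invalid-config: lambda must lie in [0, 1]")
  ctrl <- if ("group" %in% names(features)) features[features$group == "control", ] else features
  ctrl <- ctrl[stats::complete.cases(ctrl[, FEATURE_COLS]), ]
  if (nrow(ctrl) < 2)
    stop("insufficient-data: at least 2 complete control rows are required")
  X <- cbind(logit(ctrl$coupling_vl, eps), ctrl$rem_mean_bout_min,
             ctrl$one_over_f_steepness)
  colnames(X) <- c("logit_coupling", "rem_mean_bout_min", "steepness")
  mu <- colMeans(X)
  sigma <- apply(X, 2, stats::sd)
  if (any(sigma == 0))
    stop("degenerate-reference: a control feature has zero variance")
  Z <- sweep(sweep(X, 2, mu), 2, sigma, "/")
  Sigma <- stats::cov(Z)
  structure(list(mu = mu, sigma = sigma, Sigma = Sigma, lambda = lambda,
                 eps = eps, n_control = nrow(ctrl)),
            class = "control_reference")
}

#' Control z-scores for feature rows
#'
#' `z_i = (x_i - mu_i) / sigma_i` with `x = (logit coupling, REM bout min,
#' steepness)`. Orientation is preserved: larger z means tighter gating on
#' every component.
#'
#' @param features one or more `gating_features` rows.
#' @param ref a [fit_control_reference()] object.
#' @return numeric matrix (rows = subjects) with columns `z_coupling`,
#'   `z_bout`, `z_steepness`; rows with a missing feature are all-`NA` with
#'   a warning.
#' @export
control_zscore <- function(features, ref) {
  stopifnot(inherits(ref, "control_reference"),
            is.data.frame(features), all(FEATURE_COLS %in% names(features)))
  X <- cbind(logit(features$coupling_vl, ref$eps), features$rem_mean_bout_min,
             features$one_over_f_steepness)
  Z <- sweep(sweep(X, 2, ref$mu), 2, ref$sigma, "/")
  colnames(Z) <- c("z_coupling", "z_bout", "z_steepness")
  incomplete <- !stats::complete.cases(Z)
  if (any(incomplete)) {
    warning("missing feature(s): z-scores set to NA for ",
            sum(incomplete), " row(s)")
    Z[incomplete, ] <- NA_real_
  }
  rownames(Z) <- if ("subject_id" %in% names(features)) features$subject_id else NULL
  Z
}

#' Weakest-link gating summary RGI_min
#'
#' Minimum of the three oriented control-z components. Because every
#' component is oriented larger = tighter gating, the minimum is the
#' weakest link of the gate; it never exceeds any component and decreasing
#' any component can only decrease it.
#'
#' @param z numeric 3-vector (or matrix with 3 columns) of control z-scores.
#' @return scalar (or vector) RGI_min; `NA` when any component is missing.
#' @export
rgi_min <- function(z) {
  if (is.matrix(z)) return(apply(z, 1, function(r) rgi_min(as.numeric(r))))
  stopifnot(length(z) == 3)
  if (any(is.na(z))) return(NA_real_)
  min(z)
}

#' Signed shrinkage-covariance distance-to-control
#'
#' Magnitude `sqrt(z' Sigma_lambda^{-1} z)` with
#' `Sigma_lambda = (1 - lambda) * Sigma + lambda * I`, signed by the sign of
#' `mean(z)`: negative values mean net looser gating than controls. With
#' `lambda > 0` the shrunk covariance is strictly positive definite, so the
#' distance always exists.
#'
#' @param z numeric 3-vector (or 3-column matrix) of control z-scores.
#' @param ref a [fit_control_reference()] object.
#' @return signed real scalar (or vector); `NA` for missing z.
#' @export
signed_distance_to_control <- function(z, ref) {
  stopifnot(inherits(ref, "control_reference"))
  Sl <- shrink_covariance(ref$Sigma, ref$lambda)
  Slinv <- tryCatch(solve(Sl), error = function(e)
    stop("numerical-singularity: shrunk covariance not invertible (lambda = 0 with singular Sigma)"))
  one <- function(zi) {
    if (any(is.na(zi))) return(NA_real_)
    mag <- sqrt(drop(t(zi) %*% Slinv %*% zi))
    s <- sign(mean(zi))
    if (s == 0) s <- 1
    s * mag
  }
  if (is.matrix(z)) apply(z, 1, function(r) one(as.numeric(r))) else one(as.numeric(z))
}

#' Shrink a covariance matrix towards the identity
#'
#' `Sigma_lambda = (1 - lambda) * Sigma + lambda * I`. For any positive
#' semi-definite `Sigma` every eigenvalue of the result is at least
#' `lambda`, which guarantees invertibility for `lambda > 0`.
#'
#' @param Sigma symmetric positive semi-definite matrix.
#' @param lambda shrinkage weight in `[0, 1]`.
#' @return the shrunk covariance matrix.
#' @export
shrink_covariance <- function(Sigma, lambda = 0.20) {
  stopifnot(is.matrix(Sigma), nrow(Sigma) == ncol(Sigma))
  if (lambda < 0 || lambda > 1) stop("invalid-config: lambda must lie in [0, 1]")
  (1 - lambda) * Sigma + lambda * diag(nrow(Sigma))
}

#' Compute the RGI composites for a cohort
#'
#' Fits (or reuses) the control reference, z-scores every row against it,
#' and returns both composites per subject.
#'
#' @param features a `gating_features` data.frame with a `group` column.
#' @param ref optional pre-fit [fit_control_reference()]; fit from the
#'   control rows when `NULL`.
#' @param lambda shrinkage weight used when fitting the reference.
#' @return data.frame of class `rgi_result`: `subject_id`, `group`,
#'   `channel`, `z_coupling`, `z_bout`, `z_steepness`, `rgi_min`,
#'   `signed_distance`; attribute `reference` holds the fitted reference.
#' @export
compute_rgi <- function(features, ref = NULL, lambda = 0.20) {
  stopifnot(is.data.frame(features))
  if (is.null(ref)) ref <- fit_control_reference(features, lambda)
  Z <- control_zscore(features, ref)
  out <- data.frame(
    subject_id = features$subject_id,
    group = features$group,
    channel = if ("channel" %in% names(features)) features$channel else NA_character_,
    z_coupling = Z[, "z_coupling"],
    z_bout = Z[, "z_bout"],
    z_steepness = Z[, "z_steepness"],
    rgi_min = rgi_min(Z),
    signed_distance = signed_distance_to_control(Z, ref),
    stringsAsFactors = FALSE
  )
  rownames(out) <- NULL
  class(out) <- c("rgi_result", "data.frame")
  attr(out, "reference") <- ref
  out
}
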