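# Plain-text interchange: hypnogram TSV, feature and RGI CSV, epoch text
# with a JSON sidecar, and the JSON control-reference file. Numeric columns
# are written with 17 significant digits so every round-trip is bit-exact.

fmt_num <- function(x) sprintf("%.17g", x)

#' Write / read a hypnogram TSV
#'
#' Columns `stage`, `onset_s`, `duration_s`, tab-separated with a header
#' row, UTF-8.
#'
#' @param h a `hypnogram`.
#' @param path file path.
#' @return `read_hypnogram` returns a `hypnogram`; `write_hypnogram`
#'   returns `path` invisibly.
#' @export
write_hypnogram <- function(h, path) {
  stopifnot(is.data.frame(h), all(c("stage", "onset_s", "duration_s") %in% names(h)))
  out <- data.frame(stage = h$stage, onset_s = fmt_num(h$onset_s),
                    duration_s = fmt_num(h$duration_s))
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' @rdname write_hypnogram
#' @export
read_hypnogram <- function(path) {
  h <- utils::read.table(path, sep = "\t", header = TRUE,
                         colClasses = c("character", "numeric", "numeric"),
                         fileEncoding = "UTF-8")
  validate_hypnogram(h)
  class(h) <- c("hypnogram", "data.frame")
  h
}

validate_hypnogram <- function(h) {
  if (nrow(h) < 1) stop("invalid hypnogram: no bouts")
  if (any(h$duration_s <= 0)) stop("invalid hypnogram: non-positive duration")
  if (nrow(h) > 1) {
    gaps <- h$onset_s[-1] - (h$onset_s[-nrow(h)] + h$duration_s[-nrow(h)])
    if (any(abs(gaps) > 1e-6)) stop("invalid hypnogram: bouts not contiguous")
  }
  invisible(h)
}

#' Write / read a gating feature CSV
#'
#' Columns `subject_id, group, channel, coupling_vl, rem_mean_bout_min,
#' one_over_f_steepness`.
#'
#' @param features a `gating_features` data.frame.
#' @param path file path.
#' @export
write_features <- function(features, path) {
  stopifnot(is.data.frame(features))
  out <- features
  for (cl in intersect(FEATURE_COLS, names(out))) out[[cl]] <- fmt_num(out[[cl]])
  utils::write.csv(out, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  f <- utils::read.csv(path, stringsAsFactors = FALSE)
  class(f) <- c("gating_features", "data.frame")
  f
}

#' Write / read an epoch as plain text plus a JSON sidecar
#'
#' Samples go to `<path>` one value per line (17 significant digits,
#' bit-exact round-trip); `fs`, `channel` and `stage` go to
#' `<path>.json`.
#'
#' @param epoch an `epoch_signal`.
#' @param path sample file path; the sidecar is `paste0(path, ".json")`.
#' @export
write_epoch <- function(epoch, path) {
  stopifnot(inherits(epoch, "epoch_signal"))
  writeLines(fmt_num(epoch$samples), path)
  jsonlite::write_json(list(fs = epoch$fs, channel = epoch$channel,
                            stage = epoch$stage),
                       paste0(path, ".json"), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_epoch
#' @export
read_epoch <- function(path) {
  meta <- jsonlite::read_json(paste0(path, ".json"), simplifyVector = TRUE)
  structure(list(samples = as.numeric(readLines(path)),
                 fs = as.numeric(meta$fs), channel = meta$channel,
                 stage = meta$stage),
            class = "epoch_signal")
}

#' Write / read the control reference as JSON
#'
#' Stores `mu`, `sigma`, `Sigma`, `lambda`, `eps` and `n_control` so an RGI
#' run is exactly reproducible from its reference file.
#'
#' @param ref a `control_reference`.
#' @param path file path.
#' @export
write_reference <- function(ref, path) {
  stopifnot(inherits(ref, "control_reference"))
  jsonlite::write_json(list(mu = ref$mu, sigma = ref$sigma,
                            Sigma = ref$Sigma, lambda = ref$lambda,
                            eps = ref$eps, n_control = ref$n_control),
                       path, auto_unbox = TRUE, digits = NA, matrix = "rowmajor")
  invisible(path)
}

#' @rdname write_reference
#' @export
read_reference <- function(path) {
  j <- jsonlite::read_json(path, simplifyVector = TRUE)
  nm <- c("logit_coupling", "rem_mean_bout_min", "steepness")
  structure(list(mu = stats::setNames(as.numeric(j$mu), nm),
                 sigma = stats::setNames(as.numeric(j$sigma), nm),
                 Sigma = matrix(as.numeric(t(j$Sigma)), 3, 3, byrow = TRUE),
                 lambda = j$lambda, eps = j$eps, n_control = j$n_control),
            class = "control_reference")
}
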