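# End-to-end orchestration: simulate -> extract -> RGI -> stats -> model,
# driven by a single validated config with one top-level seed. Child seeds
# for every stochastic stage are drawn once from the top-level seed
# (set.seed(seed); sample.int(2^31 - 1, ...)), so identical configs give
# byte-identical outputs.

pipeline_defaults <- function() {
  list(
    seed = NULL,
    channels = c("C3-C4", "F3-F4"),
    lambda = 0.20,
    n_resamples = 20000,
    output_dir = "remgate-run",
    bands = list(so = c(0.3, 1.5), spindle = c(11, 16), fit = c(20, 45)),
    cohort = list(n_control = 4, n_epic = 4,
                  effect_sizes = list(coupling = 1, rem_bout = 1, steepness = 1),
                  feature_means = list(coupling = 0.40, rem_bout = 5.0, steepness = 2.0),
                  feature_sds = list(coupling = 0.35, rem_bout = 1.2, steepness = 0.30)),
    simulate = list(mode = "features", epoch_duration_s = 300, fs = 256, snr = 5),
    model = list(alpha = 1, beta = 1, grid = 101,
                 P_range = c(-3, 3), G_range = c(-3, 3))
  )
}

merge_known <- function(defaults, user, where) {
  unknown <- setdiff(names(user), names(defaults))
  if (length(unknown) > 0)
    stop("config error: unknown key(s) in ", where, ": ",
         paste(unknown, collapse = ", "))
  for (k in names(user)) {
    if (is.list(defaults[[k]]) && !is.null(names(defaults[[k]])) && is.list(user[[k]])) {
      defaults[[k]] <- merge_known(defaults[[k]], user[[k]], paste0(where, "$", k))
    } else {
      defaults[[k]] <- user[[k]]
    }
  }
  defaults
}

#' Validate a pipeline configuration
#'
#' Accepts a YAML file path or a named list; applies defaults, rejects
#' unknown keys, and range-checks every field. `seed` is mandatory.
#'
#' @param config path to a YAML config file, or a named list.
#' @return validated config list of class `run_config`.
#' @export
validate_config <- function(config) {
  if (is.character(config)) {
    if (!file.exists(config)) stop("config error: file not found: ", config)
    config <- yaml::read_yaml(config)
  }
  stopifnot(is.list(config))
  cfg <- merge_known(pipeline_defaults(), config, "config")
  if (is.null(cfg$seed)) stop("config error: `seed` is mandatory")
  cfg$seed <- as.integer(cfg$seed)
  if (cfg$lambda < 0 || cfg$lambda > 1)
    stop("config error: `lambda` must lie in [0, 1]")
  if (cfg$n_resamples < 1000)
    stop("config error: `n_resamples` must be >= 1000")
  if (!cfg$simulate$mode %in% c("features", "signal"))
    stop("config error: `simulate$mode` must be 'features' or 'signal'")
  for (b in c("so", "spindle", "fit")) {
    bb <- as.numeric(cfg$bands[[b]])
    if (length(bb) != 2 || bb[1] >= bb[2] || bb[1] < 0)
      stop("config error: `bands$", b, "` must be (lo, hi) with 0 <= lo < hi")
    cfg$bands[[b]] <- bb
  }
  class(cfg) <- c("run_config", "list")
  cfg
}

unlist_named <- function(x) {
  out <- unlist(x)
  stats::setNames(as.numeric(out), names(out))
}

# Realize one subject's target features as signals, then re-extract them.
simulate_subject_signals <- function(target, cfg, channel, seed) {
  set.seed(seed)
  truth <- coupling_truth(kappa = von_mises_kappa(target$coupling_vl),
                          so_freq = 0.75,
                          spindle_band = cfg$bands$spindle,
                          aperiodic_exponent = max(target$one_over_f_steepness, 0))
  ep <- synthesize_coupled_epoch(truth, duration_s = cfg$simulate$epoch_duration_s,
                                 fs = cfg$simulate$fs, snr = cfg$simulate$snr,
                                 channel = channel)
  sm <- c(W = 300, N1 = 120, N2 = 900, N3 = 600,
          REM = max(target$rem_mean_bout_min, 0.1) * 60)
  h <- generate_hypnogram(stage_mean_bouts = sm, total_s = 8 * 3600)
  extract_gating_features(ep, h, target$subject_id, target$group,
                          spindle_band = cfg$bands$spindle,
                          so_band = cfg$bands$so, fit_band = cfg$bands$fit)
}

#' Run the full gating-integrity pipeline
#'
#' Simulates a two-group cohort (feature tables directly, or full
#' signal-level synthesis followed by feature extraction), computes the RGI
#' composites per channel, runs the small-sample comparison for both
#' composites, and evaluates the misbinding-model phase space. All outputs
#' are written under `config$output_dir`: `features.csv`,
#' `rgi_<channel>.csv` and `ref_<channel>.json`, `stats.json`, `grid.csv`.
#'
#' @param config a [validate_config()] result, a YAML path, or a list.
#' @param quiet suppress progress messages.
#' @return a `run_report` list: `config`, per-channel `stats`, `files`,
#'   `warnings`.
#' @export
run_pipeline <- function(config, quiet = FALSE) {
  cfg <- if (inherits(config, "run_config")) config else validate_config(config)
  dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
  say <- function(...) if (!quiet) message(...)
  warn_log <- character(0)
  note_warn <- function(w) { warn_log <<- c(warn_log, conditionMessage(w)); invokeRestart("muffleWarning") }
  stage <- function(name, expr) {
    withCallingHandlers(
      tryCatch(expr, error = function(e)
        stop("pipeline stage '", name, "' failed: ", conditionMessage(e), call. = FALSE)),
      warning = note_warn)
  }

  n_channels <- length(cfg$channels)
  set.seed(cfg$seed)
  n_subj <- cfg$cohort$n_control + cfg$cohort$n_epic
  child <- sample.int(2^31 - 1, n_channels * (2 + n_subj) + 1)

  say("simulate + extract (", cfg$simulate$mode, " mode)")
  features <- stage("simulate", {
    out <- list()
    for (ci in seq_len(n_channels)) {
      ch <- cfg$channels[ci]
      cc <- cohort_config(n_control = cfg$cohort$n_control,
                          n_epic = cfg$cohort$n_epic,
                          effect_sizes = unlist_named(cfg$cohort$effect_sizes),
                          feature_means = unlist_named(cfg$cohort$feature_means),
                          feature_sds = unlist_named(cfg$cohort$feature_sds),
                          channel = ch, seed = child[ci])
      ftab <- generate_cohort_features(cc)
      if (cfg$simulate$mode == "signal") {
        rows <- lapply(seq_len(nrow(ftab)), function(i)
          simulate_subject_signals(ftab[i, ], cfg, ch,
                                   child[n_channels + (ci - 1) * n_subj + i]))
        ftab <- do.call(rbind, rows)
        class(ftab) <- c("gating_features", "data.frame")
      }
      out[[ch]] <- ftab
    }
    out
  })
  all_features <- do.call(rbind, features)
  rownames(all_features) <- NULL
  f_path <- file.path(cfg$output_dir, "features.csv")
  write_features(all_features, f_path)

  say("RGI composites")
  rgi <- stage("rgi", {
    lapply(cfg$channels, function(ch) {
      r <- compute_rgi(features[[ch]], lambda = cfg$lambda)
      utils::write.csv(r, file.path(cfg$output_dir,
                                    paste0("rgi_", gsub("[^A-Za-z0-9]", "", ch), ".csv")),
                       row.names = FALSE, quote = FALSE)
      write_reference(attr(r, "reference"),
                      file.path(cfg$output_dir,
                                paste0("ref_", gsub("[^A-Za-z0-9]", "", ch), ".json")))
      r
    })
  })
  names(rgi) <- cfg$channels

  say("small-sample comparisons")
  stats_out <- stage("stats", {
    res <- list()
    stats_seed_base <- n_channels * (1 + n_subj)
    for (ci in seq_len(n_channels)) {
      ch <- cfg$channels[ci]
      r <- rgi[[ch]]
      res[[ch]] <- lapply(c(rgi_min = "rgi_min", signed_distance = "signed_distance"),
        function(metric) {
          cmp <- compare_groups(r[[metric]][r$group == "epic"],
                                r[[metric]][r$group == "control"],
                                n_resamples = cfg$n_resamples,
                                seed = child[stats_seed_base + ci])
          unclass(cmp)
        })
    }
    res
  })
  provenance <- list(seed = cfg$seed, lambda = cfg$lambda,
                     n_resamples = cfg$n_resamples,
                     channels = cfg$channels, mode = cfg$simulate$mode,
                     package_version = as.character(utils::packageVersion("remgate")))
  s_path <- file.path(cfg$output_dir, "stats.json")
  jsonlite::write_json(list(provenance = provenance, results = stats_out,
                            warnings = warn_log),
                       s_path, auto_unbox = TRUE, digits = NA, pretty = TRUE)

  say("misbinding-model phase space")
  grid_path <- file.path(cfg$output_dir, "grid.csv")
  stage("model", {
    ps <- compute_phase_space(mobius_params(cfg$model$alpha, cfg$model$beta),
                              P_range = as.numeric(cfg$model$P_range),
                              G_range = as.numeric(cfg$model$G_range),
                              n_grid = cfg$model$grid)
    long <- data.frame(P_S = rep(ps$P_axis, times = length(ps$G_axis)),
                       G = rep(ps$G_axis, each = length(ps$P_axis)),
                       prob = as.vector(ps$prob))
    utils::write.csv(long, grid_path, row.names = FALSE, quote = FALSE)
  })

  structure(list(config = cfg, stats = stats_out, rgi = rgi,
                 features = all_features,
                 files = c(features = f_path, stats = s_path, grid = grid_path),
                 warnings = warn_log),
            class = "run_report")
}
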