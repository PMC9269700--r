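# Cohort-level stage transformations backing the command-line pipeline:
# each maps every trial of a materialized cohort through the corresponding
# recording-level operation and records the stage in the cohort.

stage_history <- function(cohort) attr(cohort, "history") %||% "simulate"

push_stage <- function(cohort, stage) {
  attr(cohort, "history") <- c(stage_history(cohort), stage)
  cohort
}

map_trials <- function(cohort, f) {
  for (s in seq_along(cohort$subjects)) {
    for (tr in seq_along(cohort$subjects[[s]]$trials)) {
      cohort$subjects[[s]]$trials[[tr]] <-
        f(cohort$subjects[[s]]$trials[[tr]], s, tr)
    }
  }
  cohort
}

#' Preprocess every trial of a cohort
#'
#' Applies [preprocess_emg()] (causal low-pass, decimation, high-pass) to
#' each trial's raw EMG in place.
#'
#' @param cohort an `emg_cohort` with raw trials.
#' @return The cohort with preprocessed recordings.
#' @export
preprocess_cohort <- function(cohort) {
  cohort <- map_trials(cohort, function(trial, s, tr) {
    trial$emg <- preprocess_emg(trial$emg)
    trial
  })
  push_stage(cohort, "preprocess")
}

#' Normalize every trial of a preprocessed cohort
#'
#' Applies the configured normalization per trial. For z-score, each
#' subject's training statistics are computed from the block train/test
#' split (the same seeded split the evaluation protocols use) and stored on
#' the cohort.
#'
#' @param cohort a preprocessed `emg_cohort`.
#' @param spec a [normalization_spec()].
#' @param split_seed_stream stream label for the per-subject split seeds.
#' @return The cohort with normalized recordings, splits, and (for
#'   z-score) per-subject statistics attached.
#' @export
normalize_cohort <- function(cohort, spec, split_seed_stream = 900L) {
  cfg <- cohort$config
  cohort$splits <- lapply(seq_len(cfg$n_subjects), function(s) {
    split_trials(cfg$n_trials, cfg$block_size, 0.5,
                 seed = derive_seed(cfg$seed, s, split_seed_stream))
  })
  if (spec$method == "zscore") {
    cohort$zscore_stats <- lapply(seq_len(cfg$n_subjects), function(s) {
      zscore_stats(lapply(cohort$splits[[s]]$train, function(tr) {
        cohort$subjects[[s]]$trials[[tr]]$emg$samples
      }))
    })
  }
  cohort <- map_trials(cohort, function(trial, s, tr) {
    trial$emg <- apply_normalization(trial$emg, spec,
                                     stats = cohort$zscore_stats[[s]])
    trial
  })
  cohort$normalization <- spec
  push_stage(cohort, "normalize")
}

#' Extract features for every trial of a normalized cohort
#'
#' @param cohort a normalized `emg_cohort`.
#' @param fspec a [feature_spec()].
#' @return The cohort with a `features` matrix stored per trial.
#' @export
featurize_cohort <- function(cohort, fspec = feature_spec()) {
  cohort <- map_trials(cohort, function(trial, s, tr) {
    trial$features <- assemble_features(trial$emg, fspec)
    trial
  })
  cohort$feature_spec <- fspec
  push_stage(cohort, "features")
}

#' Generate motion labels for every trial of a cohort
#'
#' Runs the position pipeline (zero-phase smoothing, inverse kinematics,
#' velocity coding) and subsamples to the feature timestamps.
#'
#' @param cohort an `emg_cohort`.
#' @return The cohort with a `labels` factor stored per trial.
#' @export
label_cohort <- function(cohort) {
  n_pos <- round(trial_duration(cohort$config) * cohort$config$fs_pos)
  kept <- kept_indices(n_pos, cohort$config$fs_pos)
  cohort <- map_trials(cohort, function(trial, s, tr) {
    trial$labels <- trial_labels(trial$motion, kept)
    trial
  })
  push_stage(cohort, "labels")
}

#' Assemble an evaluation dataset from a fully staged cohort
#'
#' Collects the per-trial features and labels of a cohort that has passed
#' through [normalize_cohort()], [featurize_cohort()] and [label_cohort()]
#' into the `emg_dataset` structure consumed by [run_protocol()].
#'
#' @param cohort a staged `emg_cohort`.
#' @return An `emg_dataset` with a single grid configuration.
#' @export
collect_dataset <- function(cohort) {
  need <- c("normalize", "features", "labels")
  missing <- setdiff(need, stage_history(cohort))
  if (length(missing)) {
    stop("cohort is missing stage(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  cfg <- cohort$config
  spec <- cohort$normalization
  fspec <- cohort$feature_spec
  grid <- evaluation_grid(methods = spec$method,
                          window_norm_ms = spec$window_ms %||% 500,
                          window_feature_ms = fspec$window_ms,
                          features = fspec$feature)
  key <- grid$key[[1]]
  subjects <- lapply(seq_len(cfg$n_subjects), function(s) {
    trials <- cohort$subjects[[s]]$trials
    feats <- do.call(rbind, lapply(trials, `[[`, "features"))
    rows_per_trial <- nrow(trials[[1]]$features)
    labs <- factor(unlist(lapply(trials, function(t) as.character(t$labels))),
                   levels = c("rest", "flexion", "extension"))
    sess <- vapply(trials, function(t) t$meta$session, integer(1))
    out <- list(features = stats::setNames(list(feats), key),
                labels = labs,
                trial = rep(seq_along(trials), each = rows_per_trial),
                session = rep(sess, each = rows_per_trial))
    out$zscore_stats <- cohort$zscore_stats[[s]]
    out
  })
  structure(list(config = cfg, grid = grid, splits = cohort$splits,
                 subjects = subjects),
            class = "emg_dataset")
}
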