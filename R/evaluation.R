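# OWN/OTHER evaluation harness: train/test splits, the processed-feature
# dataset builder, protocol runners, subject-count sweeps, rank-sum
# comparisons and the SD-vs-MAV normalization diagnostic.

#' Block-wise train/test split of trials
#'
#' Groups trials into consecutive blocks of `block_size` and randomly
#' assigns blocks so that `train_fraction` of them form the training set
#' (1:1 by default). Every block's trials land on the same side, which
#' keeps the short-timescale correlation of consecutive trials out of the
#' train/test boundary.
#'
#' @param n_trials total number of trials; must be divisible by
#'   `block_size`.
#' @param block_size trials per block.
#' @param train_fraction fraction of blocks assigned to training.
#' @param seed integer seed; the split is deterministic given the seed.
#' @return List with integer vectors `train` and `test` of trial ids.
#' @export
split_trials <- function(n_trials, block_size = 10, train_fraction = 0.5,
                         seed = 1L) {
  if (n_trials %% block_size != 0) {
    stop(sprintf("n_trials (%d) not divisible by block_size (%d)",
                 n_trials, block_size), call. = FALSE)
  }
  nb <- n_trials %/% block_size
  n_train <- round(nb * train_fraction)
  train_blocks <- with_seed(seed, sort(sample.int(nb, n_train)))
  block_of <- rep(seq_len(nb), each = block_size)
  train <- which(block_of %in% train_blocks)
  list(train = train, test = setdiff(seq_len(n_trials), train))
}

#' Evaluation grid of normalization and feature configurations
#'
#' One row per evaluated configuration. The normalization window is only
#' meaningful for SWN and is collapsed to `NA` for z-score and none (their
#' features do not depend on it).
#'
#' @param methods normalization methods to evaluate.
#' @param window_norm_ms SWN window lengths (ms) to evaluate.
#' @param window_feature_ms feature window lengths (ms) to evaluate.
#' @param features feature sets to evaluate.
#' @return A data.frame with columns `method`, `window_norm_ms`,
#'   `window_feature_ms`, `feature` and a unique `key`.
#' @export
evaluation_grid <- function(methods = c("swn", "zscore", "none"),
                            window_norm_ms = 500,
                            window_feature_ms = 500,
                            features = "ALL") {
  g <- expand.grid(method = methods, window_norm_ms = window_norm_ms,
                   window_feature_ms = window_feature_ms, feature = features,
                   stringsAsFactors = FALSE)
  g$window_norm_ms[g$method != "swn"] <- NA_real_
  g <- unique(g)
  rownames(g) <- NULL
  g$key <- grid_key(g$method, g$window_norm_ms, g$window_feature_ms, g$feature)
  g
}

grid_key <- function(method, wn, wf, feature) {
  sprintf("%s|%s|%g|%s", method,
          ifelse(is.na(wn), "-", format(wn)), wf, feature)
}

# Labels for one trial: smoothed positions -> inverse kinematics ->
# forward-difference velocity -> dead-band coding -> feature timestamps.
trial_labels <- function(motion, kept) {
  traj <- inverse_kinematics(smooth_positions(motion))
  encode_targets(traj, kept = kept)
}

#' Build the processed per-subject feature dataset of a cohort
#'
#' Runs the full processing chain for every subject and trial -
#' preprocessing, each configured normalization, feature extraction,
#' kinematic label generation, the block train/test split and the
#' z-score training statistics - and collects per-subject feature matrices
#' ready for the OWN/OTHER protocols. Raw EMG is generated (or read) one
#' trial at a time and discarded after preprocessing, so full-sized cohorts
#' fit comfortably in memory.
#'
#' @param x a [cohort_config()] (trials are simulated on the fly) or a
#'   materialized [generate_cohort()] result.
#' @param grid an [evaluation_grid()].
#' @param split_seed_stream integer stream label for the per-subject split
#'   seeds (derived from the cohort seed).
#' @param verbose print per-subject progress.
#' @return An object of class `emg_dataset`: the config, grid, per-subject
#'   splits, and per subject a list with `features` (named by grid key,
#'   each `n_trials * rows_per_trial x columns`), `labels`, `trial`,
#'   `session` row annotations and `sd_pre` (windowed SD of the
#'   preprocessed EMG, for the normalization diagnostic).
#' @export
process_cohort <- function(x, grid = evaluation_grid(),
                           split_seed_stream = 900L, verbose = FALSE) {
  if (inherits(x, "emg_cohort")) {
    cfg <- x$config
    cohort <- x
  } else {
    cfg <- validate_cohort_config(x)
    cohort <- NULL
  }
  norm_cfgs <- unique(grid[, c("method", "window_norm_ms")])
  subjects <- vector("list", cfg$n_subjects)
  splits <- vector("list", cfg$n_subjects)
  for (s in seq_len(cfg$n_subjects)) {
    if (verbose) message(sprintf("processing subject %d/%d", s, cfg$n_subjects))
    prof <- if (is.null(cohort)) subject_profile(s, cfg) else
      cohort$subjects[[s]]$profile
    schedule <- movement_schedule(cfg, s)
    pre <- vector("list", cfg$n_trials)
    labels <- vector("list", cfg$n_trials)
    session <- integer(cfg$n_trials)
    kept <- NULL
    for (tr in seq_len(cfg$n_trials)) {
      trial <- if (is.null(cohort)) simulate_trial(cfg, prof, tr, schedule)
               else cohort$subjects[[s]]$trials[[tr]]
      rec <- preprocess_emg(trial$emg)
      if (is.null(kept)) kept <- kept_indices(nrow(rec$samples), rec$fs)
      pre[[tr]] <- rec$samples
      labels[[tr]] <- trial_labels(trial$motion, kept)
      session[tr] <- trial$meta$session
    }
    split <- split_trials(cfg$n_trials, cfg$block_size, 0.5,
                          seed = derive_seed(cfg$seed, s, split_seed_stream))
    zstats <- zscore_stats(pre[split$train])
    rows_per_trial <- length(kept)
    features <- vector("list", nrow(grid))
    names(features) <- grid$key
    for (gi in seq_len(nrow(grid))) {
      fspec <- feature_spec(grid$feature[gi],
                            window_ms = grid$window_feature_ms[gi])
      mats <- vector("list", cfg$n_trials)
      for (tr in seq_len(cfg$n_trials)) {
        samples <- switch(grid$method[gi],
          none = pre[[tr]],
          zscore = sweep(sweep(pre[[tr]], 2, zstats$mean), 2, zstats$sd, "/"),
          swn = swn_stream(pre[[tr]],
                           window_samples(grid$window_norm_ms[gi], 500))$y)
        rec <- emg_recording(samples, 500, stage = "normalized")
        rec$stage <- "normalized"
        mats[[tr]] <- assemble_features(rec, fspec)
      }
      features[[gi]] <- do.call(rbind, mats)
    }
    aux <- lapply(pre, function(m) {
      windowed_aux(emg_recording(m, 500, stage = "preprocessed"))
    })
    sd_pre <- do.call(rbind, lapply(aux, `[[`, "sd"))
    mav_pre <- do.call(rbind, lapply(aux, `[[`, "mav"))
    cmav_pre <- do.call(rbind, lapply(aux, `[[`, "cmav"))
    subjects[[s]] <- list(
      features = features,
      labels = factor(unlist(lapply(labels, as.character)),
                      levels = c("rest", "flexion", "extension")),
      trial = rep(seq_len(cfg$n_trials), each = rows_per_trial),
      session = rep(session, each = rows_per_trial),
      sd_pre = sd_pre,
      mav_pre = mav_pre,
      cmav_pre = cmav_pre,
      zscore_stats = zstats
    )
    splits[[s]] <- split
  }
  structure(list(config = cfg, grid = grid, splits = splits,
                 subjects = subjects),
            class = "emg_dataset")
}

#' @export
print.emg_dataset <- function(x, ...) {
  cat(sprintf("<emg_dataset> %d subjects, %d grid configuration(s), %d rows/subject\n",
              length(x$subjects), nrow(x$grid),
              length(x$subjects[[1]]$labels)))
  invisible(x)
}

subject_rows <- function(sub, trials) which(sub$trial %in% trials)

fit_and_score <- function(train_x, train_y, test_x, test_y, ...) {
  fit <- train_classifier(train_x, train_y, ...)
  list(accuracy = accuracy(predict(fit, test_x), test_y), fit = fit)
}

#' Run the OWN or OTHER evaluation protocol
#'
#' OWN: for every subject, trains on the subject's own training split and
#' tests on their own test split. OTHER: for every held-out subject, trains
#' on the pooled training splits of `n_train_subjects` drawn from the
#' remaining subjects (every combination, or a seeded subsample capped by
#' `max_combinations`) and tests on the held-out subject's test split. The
#' held-out subject never contributes training data; z-score features were
#' normalized per subject with that subject's own training statistics
#' (the calibration the z-score baseline requires).
#'
#' @param dataset an [process_cohort()] result.
#' @param model_type `"OWN"` or `"OTHER"`.
#' @param n_train_subjects training-pool size for OTHER (1 to n-1).
#' @param max_combinations cap on the number of training-subject
#'   combinations per held-out subject (seeded subsample when exceeded).
#' @param seed seed for the combination subsample.
#' @param keys grid keys to evaluate (default: all in the dataset).
#' @param ... passed to [train_classifier()].
#' @return An `emg_evaluation` data.frame with one row per
#'   (configuration, test subject, combination): `test_subject`,
#'   `model_type`, `method`, window lengths, `feature`,
#'   `n_train_subjects`, `combination`, `accuracy`.
#' @export
run_protocol <- function(dataset, model_type = c("OWN", "OTHER"),
                         n_train_subjects = NULL, max_combinations = Inf,
                         seed = 1L, keys = NULL, ...) {
  model_type <- match.arg(model_type)
  stopifnot(inherits(dataset, "emg_dataset"))
  grid <- dataset$grid
  if (!is.null(keys)) grid <- grid[grid$key %in% keys, , drop = FALSE]
  n_sub <- length(dataset$subjects)
  if (model_type == "OTHER") {
    if (is.null(n_train_subjects)) n_train_subjects <- n_sub - 1L
    if (n_train_subjects < 1 || n_train_subjects > n_sub - 1) {
      stop("n_train_subjects must be in [1, n_subjects - 1]", call. = FALSE)
    }
  }
  out <- list()
  warm_coef <- list()
  for (gi in seq_len(nrow(grid))) {
    key <- grid$key[gi]
    for (s in seq_len(n_sub)) {
      sub <- dataset$subjects[[s]]
      test_idx <- subject_rows(sub, dataset$splits[[s]]$test)
      test_x <- sub$features[[key]][test_idx, , drop = FALSE]
      test_y <- sub$labels[test_idx]
      if (model_type == "OWN") {
        train_idx <- subject_rows(sub, dataset$splits[[s]]$train)
        acc <- fit_and_score(sub$features[[key]][train_idx, , drop = FALSE],
                             sub$labels[train_idx], test_x, test_y,
                             ...)$accuracy
        out[[length(out) + 1]] <- data.frame(
          test_subject = s, model_type = model_type,
          method = grid$method[gi],
          window_norm_ms = grid$window_norm_ms[gi],
          window_feature_ms = grid$window_feature_ms[gi],
          feature = grid$feature[gi],
          n_train_subjects = NA_integer_, combination = NA_character_,
          accuracy = acc)
      } else {
        others <- setdiff(seq_len(n_sub), s)
        combos <- utils::combn(others, n_train_subjects, simplify = FALSE)
        if (length(combos) > max_combinations) {
          pick <- with_seed(derive_seed(seed, gi, s),
                            sample.int(length(combos), max_combinations))
          combos <- combos[sort(pick)]
        }
        for (combo in combos) {
          train_x <- do.call(rbind, lapply(combo, function(o) {
            so <- dataset$subjects[[o]]
            so$features[[key]][subject_rows(so, dataset$splits[[o]]$train), ,
                               drop = FALSE]
          }))
          train_y <- factor(unlist(lapply(combo, function(o) {
            so <- dataset$subjects[[o]]
            as.character(so$labels[subject_rows(so, dataset$splits[[o]]$train)])
          })), levels = levels(sub$labels))
          # successive pools per configuration overlap heavily; warm-start
          # from the previous fit of the same configuration
          res <- fit_and_score(train_x, train_y, test_x, test_y,
                               init = warm_coef[[key]], ...)
          acc <- res$accuracy
          warm_coef[[key]] <- res$fit$coef
          out[[length(out) + 1]] <- data.frame(
            test_subject = s, model_type = model_type,
            method = grid$method[gi],
            window_norm_ms = grid$window_norm_ms[gi],
            window_feature_ms = grid$window_feature_ms[gi],
            feature = grid$feature[gi],
            n_train_subjects = n_train_subjects,
            combination = paste(combo, collapse = "+"),
            accuracy = acc)
        }
      }
    }
  }
  res <- do.call(rbind, out)
  class(res) <- c("emg_evaluation", class(res))
  res
}

#' Summarize an evaluation: mean and SD of accuracy per configuration
#'
#' Aggregates accuracy over test subjects (and training combinations) for
#' every (model type, method, window, feature, training-pool size) cell.
#' With `per_subject = TRUE` subject means are taken first, so the reported
#' SD is across subjects; otherwise it is across all subject x combination
#' cells.
#'
#' @param result an `emg_evaluation` from [run_protocol()].
#' @param per_subject average combinations within subject first.
#' @return Data.frame of group means, SDs and cell counts.
#' @export
summarize_evaluation <- function(result, per_subject = TRUE) {
  by_cols <- c("model_type", "method", "window_norm_ms",
               "window_feature_ms", "feature", "n_train_subjects")
  df <- as.data.frame(result)
  df$window_norm_ms[is.na(df$window_norm_ms)] <- -1
  df$n_train_subjects[is.na(df$n_train_subjects)] <- -1L
  if (per_subject) {
    df <- stats::aggregate(accuracy ~ test_subject + model_type + method +
                             window_norm_ms + window_feature_ms + feature +
                             n_train_subjects, data = df, FUN = mean)
  }
  agg <- stats::aggregate(accuracy ~ model_type + method + window_norm_ms +
                            window_feature_ms + feature + n_train_subjects,
                          data = df,
                          FUN = function(a) c(mean = mean(a), sd = sd(a),
                                              n = length(a)))
  out <- cbind(agg[by_cols], as.data.frame(agg$accuracy))
  out$window_norm_ms[out$window_norm_ms == -1] <- NA_real_
  out$n_train_subjects[out$n_train_subjects == -1L] <- NA_integer_
  out
}

#' Best-over-window-grid accuracy per method
#'
#' Implements the window-selection comparison rule: per subject and
#' (model type, method, feature), take the maximum mean accuracy over the
#' evaluated window grid, then average over subjects. `per_subject = FALSE`
#' instead maximizes the group mean over the grid.
#'
#' @param result an `emg_evaluation`.
#' @param per_subject maximize per subject (default) or on group means.
#' @return Data.frame with mean and SD of the selected accuracies.
#' @export
best_window_accuracy <- function(result, per_subject = TRUE) {
  df <- as.data.frame(result)
  df <- stats::aggregate(accuracy ~ test_subject + model_type + method +
                           feature + window_norm_ms + window_feature_ms,
                         data = df, FUN = mean, na.action = stats::na.pass)
  if (per_subject) {
    best <- stats::aggregate(accuracy ~ test_subject + model_type + method +
                               feature, data = df, FUN = max)
    out <- stats::aggregate(accuracy ~ model_type + method + feature,
                            data = best,
                            FUN = function(a) c(mean = mean(a), sd = sd(a)))
    cbind(out[c("model_type", "method", "feature")],
          as.data.frame(out$accuracy))
  } else {
    grp <- stats::aggregate(accuracy ~ model_type + method + feature +
                              window_norm_ms + window_feature_ms,
                            data = df, FUN = mean, na.action = stats::na.pass)
    stats::aggregate(accuracy ~ model_type + method + feature, data = grp,
                     FUN = max)
  }
}

#' Sweep the number of training subjects for the OTHER protocol
#'
#' Re-runs the OTHER protocol for each training-pool size `k`, typically
#' 1 to n-1, per normalization method.
#'
#' @param dataset an [process_cohort()] result.
#' @param ks training-pool sizes.
#' @param keys grid keys to evaluate (default: all).
#' @param max_combinations,seed,... as in [run_protocol()].
#' @return An `emg_evaluation` with one row per (k, configuration,
#'   subject, combination).
#' @export
sweep_subject_counts <- function(dataset, ks = NULL, keys = NULL,
                                 max_combinations = Inf, seed = 1L, ...) {
  n_sub <- length(dataset$subjects)
  if (is.null(ks)) ks <- seq_len(n_sub - 1L)
  res <- lapply(ks, function(k) {
    run_protocol(dataset, "OTHER", n_train_subjects = k,
                 max_combinations = max_combinations,
                 seed = derive_seed(seed, k), keys = keys, ...)
  })
  out <- do.call(rbind, res)
  class(out) <- c("emg_evaluation", class(out))
  out
}

#' Compare two accuracy groups (Wilcoxon rank-sum + Bonferroni)
#'
#' Two-sided Wilcoxon rank-sum test (exact when sample sizes permit and no
#' ties are present, as R defaults) with Bonferroni adjustment
#' `min(1, p * n_comparisons)`.
#'
#' @param accuracies_a,accuracies_b numeric vectors (size >= 2 each).
#' @param n_comparisons number of comparisons in the family.
#' @return Named vector with `p_raw` and `p_adjusted`.
#' @export
compare_groups <- function(accuracies_a, accuracies_b, n_comparisons = 1) {
  if (length(accuracies_a) < 2 || length(accuracies_b) < 2) {
    stop("both groups need at least 2 values", call. = FALSE)
  }
  p <- suppressWarnings(
    wilcox.test(accuracies_a, accuracies_b, alternative = "two.sided")$p.value)
  c(p_raw = p,
    p_adjusted = p.adjust(p, method = "bonferroni", n = n_comparisons))
}

find_mav_key <- function(dataset, method) {
  g <- dataset$grid
  cand <- g$key[g$method == method & g$feature %in% c("ALL", "MAV")]
  if (length(cand) == 0) {
    stop(sprintf("dataset has no MAV-bearing feature configuration for method \"%s\"",
                 method), call. = FALSE)
  }
  cand[[1]]
}

#' Correlation between windowed EMG standard deviation and MAV
#'
#' For every subject and channel, the Pearson correlation between the
#' windowed SD of the preprocessed (pre-normalization) EMG and the MAV of
#' the normalized signal over the same windows. A strongly positive mean
#' correlation indicates that amplitude features inherit the signal's SD -
#' and with it every subject- and session-level amplitude fluctuation;
#' normalizing each window away from its own scale removes that
#' dependence.
#'
#' Two readings of "MAV of the normalized signal" exist because the
#' normalization and feature windows slide independently:
#'
#' * `mav = "window"` (default) normalizes the whole window at each
#'   timestep (the per-window transform of [swn_window()]) and takes its
#'   mean absolute value, `mean(|x - m_t|) / s_t`. This is the
#'   window-statistics analysis; under SWN it yields the weakly negative
#'   correlation characteristic of windows that mix quiet and active
#'   segments.
#' * `mav = "stream"` correlates the pipeline's actual MAV feature
#'   (computed on the stream of newest normalized samples). Streaming SWN
#'   deliberately preserves local amplitude *change*, so transition
#'   windows keep a mild positive coupling to the signal SD.
#'
#' For `"none"` both readings coincide; for `"zscore"` the window reading
#' uses the per-subject training statistics (a per-channel affine map, so
#' its correlation matches the unnormalized one up to the mean offset).
#'
#' @param dataset an [process_cohort()] result (for `mav = "stream"` its
#'   grid must contain an `ALL` or `MAV` configuration for `method`).
#' @param method `"none"`, `"swn"` or `"zscore"`.
#' @param mav `"window"` or `"stream"` (see above).
#' @return List with `table` (subject, channel, correlation; `NA` when a
#'   series is constant) and `mean_correlation` over finite entries.
#' @export
sd_feature_correlation <- function(dataset, method = c("none", "swn", "zscore"),
                                   mav = c("window", "stream")) {
  method <- match.arg(method)
  mav <- match.arg(mav)
  rows <- list()
  for (s in seq_along(dataset$subjects)) {
    sub <- dataset$subjects[[s]]
    if (mav == "stream") {
      key <- find_mav_key(dataset, method)
      feats <- sub$features[[key]]
      mav_mat <- feats[, grep("_MAV$", colnames(feats)), drop = FALSE]
    } else {
      mav_mat <- switch(method,
        none = sub$mav_pre,
        swn = sub$cmav_pre / sub$sd_pre,
        zscore = sweep(sub$mav_pre, 2, sub$zscore_stats$sd, "/"))
    }
    for (ch in seq_len(ncol(mav_mat))) {
      sd_series <- sub$sd_pre[, ch]
      mav_series <- mav_mat[, ch]
      ok <- is.finite(sd_series) & is.finite(mav_series)
      r <- if (sd(sd_series[ok]) == 0 || sd(mav_series[ok]) == 0) NA_real_
           else cor(sd_series[ok], mav_series[ok])
      rows[[length(rows) + 1]] <- data.frame(subject = s, channel = ch,
                                             correlation = r)
    }
  }
  table <- do.call(rbind, rows)
  list(table = table,
       mean_correlation = mean(table$correlation, na.rm = TRUE))
}

#' Held-out accuracy with shuffled training labels (chance-level check)
#'
#' Per subject, permutes the training labels (breaking any feature-label
#' association), trains the classifier on the shuffled training split and
#' scores it on the true test labels. With three classes and a
#' class-balanced fit the expected accuracy is the 33.3% chance level.
#'
#' @param dataset an [process_cohort()] result.
#' @param key grid key to use (default: first).
#' @param seed seed for the label permutations.
#' @param subjects subject indices to evaluate (default: all).
#' @param ... passed to [train_classifier()].
#' @return List with per-subject accuracies and their mean.
#' @export
shuffled_label_chance <- function(dataset, key = NULL, seed = 1L,
                                  subjects = NULL, ...) {
  if (is.null(key)) key <- dataset$grid$key[[1]]
  if (is.null(subjects)) subjects <- seq_along(dataset$subjects)
  accs <- vapply(subjects, function(s) {
    sub <- dataset$subjects[[s]]
    train_idx <- subject_rows(sub, dataset$splits[[s]]$train)
    test_idx <- subject_rows(sub, dataset$splits[[s]]$test)
    y_shuf <- with_seed(derive_seed(seed, s),
                        sample(sub$labels[train_idx]))
    fit_and_score(sub$features[[key]][train_idx, , drop = FALSE], y_shuf,
                  sub$features[[key]][test_idx, , drop = FALSE],
                  sub$labels[test_idx], ...)$accuracy
  }, numeric(1))
  list(accuracies = accs, mean_accuracy = mean(accs))
}
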