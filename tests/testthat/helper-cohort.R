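# Shared fixtures: reduced cohort configurations and a lazily built,
# cached processed dataset so expensive pipeline objects are computed once
# per test run.

tiny_config <- function(...) {
  cohort_config(n_subjects = 2, n_trials = 20, session_size = 10,
                seed = 7L, ...)
}

.fixture_cache <- new.env(parent = emptyenv())

cached <- function(name, expr) {
  if (!exists(name, envir = .fixture_cache)) {
    assign(name, force(expr), envir = .fixture_cache)
  }
  get(name, envir = .fixture_cache)
}

# A small heterogeneous 3-subject dataset with all three normalizations.
small_dataset <- function() {
  cached("small_dataset", {
    cfg <- cohort_config(n_subjects = 3, n_trials = 40, session_size = 20,
                         seed = 11L)
    suppressWarnings(process_cohort(cfg, evaluation_grid()))
  })
}

# A homogeneous (exchangeable-subject) counterpart.
homog_dataset <- function() {
  cached("homog_dataset", {
    cfg <- cohort_config(n_subjects = 3, n_trials = 40, session_size = 20,
                         seed = 11L, gain_spread = 0, snr_spread = 0,
                         session_spread = 0, trial_spread = 0)
    suppressWarnings(process_cohort(cfg, evaluation_grid()))
  })
}

# One preprocessed full-length trial for feature/normalization tests.
one_preprocessed_trial <- function() {
  cached("one_trial", {
    cfg <- tiny_config()
    prof <- subject_profile(1, cfg)
    trial <- emgswn:::simulate_trial(cfg, prof, 3)
    list(cfg = cfg, prof = prof, trial = trial,
         pre = preprocess_emg(trial$emg))
  })
}
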