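#' Cohort configuration for the synthetic EMG experiment
#'
#' Defines the study conditions emulated by the simulator: trial structure
#' (2 s pre-rest, 2.5 s task, 0.1 s post-rest), 12 elbow movement tasks among
#' four targets, 360 trials per subject in sessions of 36, 12 EMG channels at
#' 2000 Hz and planar marker positions at 500 Hz, plus the heterogeneity
#' parameters that create the inter-subject amplitude differences motivating
#' sliding-window normalization.
#'
#' Heterogeneity is multiplicative and log-normal throughout (median 1):
#' `gain_spread` scales each subject's per-channel amplitude,
#' `snr_spread` scales each subject's activation-to-noise-floor ratio,
#' `session_spread` drifts channel gains between recording sessions, and
#' `trial_spread` jitters them between trials. Setting all four to zero
#' yields statistically exchangeable subjects.
#'
#' @param n_subjects number of subjects in the cohort.
#' @param n_channels number of EMG channels.
#' @param n_trials trials per subject; must be divisible by `block_size`.
#' @param fs_emg EMG sampling rate in Hz.
#' @param fs_pos marker-position sampling rate in Hz; `fs_emg` must be an
#'   integer multiple.
#' @param pre_rest_s,task_s,post_rest_s trial phase durations in seconds.
#' @param target_angles elbow target angles in degrees (0 = fully extended
#'   arm); all ordered pairs of distinct targets define the movement tasks.
#' @param upper_arm_m,forearm_m limb lengths in metres.
#' @param shoulder_angle_deg constant shoulder angle during trials.
#' @param gain_spread log-SD of per-subject per-channel amplitude gains.
#' @param snr_spread log-SD of the per-subject activation gain multiplier.
#' @param session_spread log-SD of per-session per-channel gain drift.
#' @param trial_spread log-SD of per-trial per-channel gain jitter.
#' @param noise_floor baseline EMG amplitude (arbitrary units) at rest.
#' @param activation_per_degps envelope amplitude added per deg/s of elbow
#'   angular velocity on an active channel.
#' @param emd_lead_s electromechanical lead: the activation envelope precedes
#'   movement by this many seconds.
#' @param carrier_band EMG carrier passband in Hz (length 2).
#' @param n_flexor,n_extensor counts of flexion- and extension-associated
#'   channels; the remainder are neutral. Defaults mirror a 12-channel
#'   elbow montage (6 flexor-side, 5 extensor-side, 1 wrist).
#' @param pos_noise_m SD of marker measurement jitter in metres.
#' @param move_duration_range range (seconds) the movement duration is drawn
#'   from; must fit inside `task_s`.
#' @param allow_rest_trials permit tasks whose start and end targets match.
#' @param session_size trials per recording session.
#' @param block_size consecutive-trial block size used by the train/test
#'   split.
#' @param seed root seed for the cohort; all per-subject and per-trial seeds
#'   derive from it.
#'
#' @return An object of class `cohort_config` (a validated list).
#' @export
cohort_config <- function(n_subjects = 10,
                          n_channels = 12,
                          n_trials = 360,
                          fs_emg = 2000,
                          fs_pos = 500,
                          pre_rest_s = 2.0,
                          task_s = 2.5,
                          post_rest_s = 0.1,
                          target_angles = c(30, 60, 90, 120),
                          upper_arm_m = 0.30,
                          forearm_m = 0.25,
                          shoulder_angle_deg = 45,
                          gain_spread = 0.6,
                          snr_spread = 0.5,
                          session_spread = 0.3,
                          trial_spread = 0.15,
                          noise_floor = 0.02,
                          activation_per_degps = 0.002,
                          emd_lead_s = 0.05,
                          carrier_band = c(20, 450),
                          n_flexor = 6,
                          n_extensor = 5,
                          pos_noise_m = 1e-5,
                          move_duration_range = c(0.8, 1.8),
                          allow_rest_trials = FALSE,
                          session_size = 36,
                          block_size = 10,
                          seed = 1L) {
  cfg <- list(
    n_subjects = as.integer(n_subjects), n_channels = as.integer(n_channels),
    n_trials = as.integer(n_trials), fs_emg = fs_emg, fs_pos = fs_pos,
    pre_rest_s = pre_rest_s, task_s = task_s, post_rest_s = post_rest_s,
    target_angles = target_angles, upper_arm_m = upper_arm_m,
    forearm_m = forearm_m, shoulder_angle_deg = shoulder_angle_deg,
    gain_spread = gain_spread, snr_spread = snr_spread,
    session_spread = session_spread, trial_spread = trial_spread,
    noise_floor = noise_floor, activation_per_degps = activation_per_degps,
    emd_lead_s = emd_lead_s, carrier_band = carrier_band,
    n_flexor = as.integer(n_flexor), n_extensor = as.integer(n_extensor),
    pos_noise_m = pos_noise_m, move_duration_range = move_duration_range,
    allow_rest_trials = isTRUE(allow_rest_trials),
    session_size = as.integer(session_size),
    block_size = as.integer(block_size), seed = as.integer(seed)
  )
  validate_cohort_config(cfg)
}

validate_cohort_config <- function(cfg) {
  for (f in c("n_subjects", "n_channels", "n_trials", "fs_emg", "fs_pos",
              "pre_rest_s", "task_s", "post_rest_s", "upper_arm_m",
              "forearm_m", "noise_floor", "activation_per_degps",
              "session_size", "block_size")) {
    stopifnot_scalar_pos(cfg[[f]], f)
  }
  if (cfg$n_trials %% cfg$block_size != 0L) {
    stop("`n_trials` must be divisible by the split block size (",
         cfg$block_size, ")", call. = FALSE)
  }
  if (cfg$fs_emg %% cfg$fs_pos != 0) {
    stop("`fs_emg` must be an integer multiple of `fs_pos`", call. = FALSE)
  }
  if (any(cfg$target_angles <= 0) || any(cfg$target_angles >= 180)) {
    stop("`target_angles` must lie strictly between 0 and 180 degrees",
         call. = FALSE)
  }
  if (anyDuplicated(cfg$target_angles)) {
    stop("`target_angles` must be distinct", call. = FALSE)
  }
  for (f in c("gain_spread", "snr_spread", "session_spread", "trial_spread",
              "emd_lead_s", "pos_noise_m")) {
    if (cfg[[f]] < 0) stop(sprintf("`%s` must be >= 0", f), call. = FALSE)
  }
  if (length(cfg$carrier_band) != 2 || cfg$carrier_band[1] <= 0 ||
      cfg$carrier_band[2] <= cfg$carrier_band[1] ||
      cfg$carrier_band[2] >= cfg$fs_emg / 2) {
    stop("`carrier_band` must be 0 < low < high < fs_emg/2", call. = FALSE)
  }
  if (cfg$n_flexor < 1 || cfg$n_extensor < 1 ||
      cfg$n_flexor + cfg$n_extensor > cfg$n_channels) {
    stop("need at least one flexor and one extensor channel, and ",
         "n_flexor + n_extensor <= n_channels", call. = FALSE)
  }
  if (length(cfg$move_duration_range) != 2 ||
      cfg$move_duration_range[1] <= 0 ||
      cfg$move_duration_range[2] < cfg$move_duration_range[1] ||
      cfg$move_duration_range[2] > cfg$task_s) {
    stop("`move_duration_range` must satisfy 0 < lo <= hi <= task_s",
         call. = FALSE)
  }
  structure(cfg, class = "cohort_config")
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  %d subjects x %d trials, %d EMG channels @ %g Hz, positions @ %g Hz\n",
              x$n_subjects, x$n_trials, x$n_channels, x$fs_emg, x$fs_pos))
  cat(sprintf("  trial: %.1fs pre-rest + %.1fs task + %.1fs post-rest; targets: %s deg\n",
              x$pre_rest_s, x$task_s, x$post_rest_s,
              paste(x$target_angles, collapse = ", ")))
  cat(sprintf("  heterogeneity (log-SD): gain %.2f, snr %.2f, session %.2f, trial %.2f\n",
              x$gain_spread, x$snr_spread, x$session_spread, x$trial_spread))
  cat(sprintf("  seed: %d\n", x$seed))
  invisible(x)
}

# Duration of one trial in seconds.
trial_duration <- function(cfg) cfg$pre_rest_s + cfg$task_s + cfg$post_rest_s

# The 12 movement tasks: all ordered pairs of distinct target angles.
movement_table <- function(cfg) {
  k <- length(cfg$target_angles)
  idx <- expand.grid(start = seq_len(k), end = seq_len(k))
  idx <- idx[idx$start != idx$end, , drop = FALSE]
  data.frame(start_angle = cfg$target_angles[idx$start],
             end_angle = cfg$target_angles[idx$end])
}

# Per-subject movement schedule: shuffled cycles through the movement table,
# truncated to n_trials, so every session of 36 trials contains each of the
# 12 movements three times under the defaults.
movement_schedule <- function(cfg, subject) {
  moves <- movement_table(cfg)
  n_cycles <- ceiling(cfg$n_trials / nrow(moves))
  order <- with_seed(derive_seed(cfg$seed, subject, 101L), {
    unlist(lapply(seq_len(n_cycles), function(i) sample.int(nrow(moves))))
  })
  moves[order[seq_len(cfg$n_trials)], , drop = FALSE]
}

#' Subject profile: per-channel gains, roles and limb lengths
#'
#' Draws the multiplicative amplitude structure of one synthetic subject:
#' per-channel gains (log-normal, log-SD `gain_spread`), a subject-level
#' activation gain multiplier (log-SD `snr_spread`), per-session channel
#' drift (log-SD `session_spread`), channel roles (flexor / extensor /
#' neutral) and slightly individual limb lengths.
#'
#' @param subject_id integer subject index (1-based).
#' @param config a [cohort_config()].
#' @return An object of class `subject_profile`.
#' @export
subject_profile <- function(subject_id, config) {
  cfg <- config
  n_sessions <- ceiling(cfg$n_trials / cfg$session_size)
  prof <- with_seed(derive_seed(cfg$seed, subject_id, 1L), {
    list(
      subject_id = as.integer(subject_id),
      channel_gains = exp(rnorm(cfg$n_channels, 0, cfg$gain_spread)),
      snr_gain = exp(rnorm(1, 0, cfg$snr_spread)),
      session_gains = matrix(
        exp(rnorm(n_sessions * cfg$n_channels, 0, cfg$session_spread)),
        nrow = n_sessions, ncol = cfg$n_channels),
      upper_arm_m = cfg$upper_arm_m * exp(rnorm(1, 0, 0.03)),
      forearm_m = cfg$forearm_m * exp(rnorm(1, 0, 0.03))
    )
  })
  prof$channel_roles <- rep(c("flexor", "extensor", "neutral"),
                            c(cfg$n_flexor, cfg$n_extensor,
                              cfg$n_channels - cfg$n_flexor - cfg$n_extensor))
  stopifnot(all(prof$channel_gains > 0))
  structure(prof, class = "subject_profile")
}
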