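# Synthetic multi-subject EMG + marker-position cohorts.
#
# Generative model: each channel carries band-limited Gaussian noise
# (the carrier, 20-450 Hz) amplitude-modulated by an activation envelope.
# The envelope is the channel's noise floor plus a term proportional to the
# rectified elbow angular velocity (flexor channels respond to positive,
# extensor to negative velocity, neutral channels to neither), smoothed and
# led by a small electromechanical delay. Per-subject, per-session and
# per-trial log-normal gains create the amplitude heterogeneity that
# motivates sliding-window normalization.

# Band-limit white Gaussian noise to the carrier band by spectral masking
# (ideal band edges), rescaled so each column has unit variance in
# expectation; the activation envelope is then the RMS amplitude directly.
band_limit_carrier <- function(x, cfg) {
  n <- nrow(x)
  freq <- (seq_len(n) - 1) / n * cfg$fs_emg
  folded <- pmin(freq, cfg$fs_emg - freq)
  keep <- folded >= cfg$carrier_band[1] & folded <= cfg$carrier_band[2]
  scale <- 1 / sqrt(mean(keep))
  apply(x, 2, function(col) {
    X <- fft(col)
    X[!keep] <- 0
    Re(fft(X, inverse = TRUE)) / n * scale
  })
}

# Activation envelope at the position sampling rate: rectified velocity,
# shifted earlier by the electromechanical lead and smoothed with a 100 ms
# moving average (edges replicated).
activation_envelope <- function(vel, role, cfg) {
  e <- switch(role,
              flexor = pmax(vel, 0),
              extensor = pmax(-vel, 0),
              neutral = rep(0, length(vel)))
  n <- length(e)
  lead <- round(cfg$emd_lead_s * cfg$fs_pos)
  if (lead > 0) e <- c(e[(lead + 1):n], rep(e[n], lead))
  k <- max(1L, round(0.1 * cfg$fs_pos))
  if (k %% 2 == 0) k <- k + 1L
  half <- (k - 1L) %/% 2L
  padded <- c(rep(e[1], half), e, rep(e[n], half))
  sm <- as.numeric(stats::filter(padded, rep(1 / k, k), sides = 2))
  sm[(half + 1):(half + n)]
}

#' Synthesize one trial of multi-channel EMG from a joint trajectory
#'
#' @param trajectory a `joint_trajectory` covering the full trial.
#' @param profile a [subject_profile()].
#' @param config a [cohort_config()].
#' @param seed integer seed for the carrier noise and trial gain jitter.
#' @param session session index used to select the session gain drift row.
#' @return An `emg_recording` at stage `raw`, `fs = config$fs_emg`.
#' @export
synthesize_trial_emg <- function(trajectory, profile, config, seed = 1L,
                                 session = 1L) {
  cfg <- config
  n_pos <- length(trajectory$theta_elb)
  if (n_pos < 2) stop("zero-length trajectory", call. = FALSE)
  ratio <- cfg$fs_emg / cfg$fs_pos
  n_emg <- n_pos * ratio
  vel <- elbow_velocity(trajectory$theta_elb, trajectory$fs)
  out <- with_seed(seed, {
    carrier <- matrix(rnorm(n_emg * cfg$n_channels), n_emg, cfg$n_channels)
    trial_gain <- exp(rnorm(cfg$n_channels, 0, cfg$trial_spread))
    list(carrier = band_limit_carrier(carrier, cfg),
         trial_gain = trial_gain)
  })
  t_pos <- (seq_len(n_pos) - 1) / cfg$fs_pos
  t_emg <- (seq_len(n_emg) - 1) / cfg$fs_emg
  sess_gain <- profile$session_gains[min(session, nrow(profile$session_gains)), ]
  emg <- out$carrier
  for (ch in seq_len(cfg$n_channels)) {
    env_pos <- cfg$noise_floor +
      profile$snr_gain * cfg$activation_per_degps *
      activation_envelope(vel, profile$channel_roles[ch], cfg)
    env <- approx(t_pos, env_pos, xout = t_emg, rule = 2)$y
    amp <- profile$channel_gains[ch] * sess_gain[ch] * out$trial_gain[ch]
    emg[, ch] <- emg[, ch] * (amp * env)
  }
  emg_recording(emg, cfg$fs_emg, stage = "raw",
                meta = list(subject = profile$subject_id,
                            session = as.integer(session),
                            start_angle = trajectory$start_angle,
                            end_angle = trajectory$end_angle))
}

# Generate the true trajectory, noisy marker positions and raw EMG for one
# (subject, trial); the single source of truth for trial-level seeding.
simulate_trial <- function(cfg, profile, trial, schedule = NULL) {
  if (is.null(schedule)) schedule <- movement_schedule(cfg, profile$subject_id)
  mv <- schedule[trial, ]
  session <- ((trial - 1L) %/% cfg$session_size) + 1L
  traj <- generate_trajectory(mv$start_angle, mv$end_angle, cfg,
                              seed = derive_seed(cfg$seed, profile$subject_id,
                                                 trial, 2L))
  fk <- forward_kinematics(traj$theta_sld, traj$theta_elb,
                           profile$upper_arm_m, profile$forearm_m)
  n <- length(traj$theta_elb)
  jitter <- with_seed(derive_seed(cfg$seed, profile$subject_id, trial, 3L),
                      matrix(rnorm(n * 6, 0, cfg$pos_noise_m), n, 6))
  motion <- motion_recording(
    hand = fk$hand + jitter[, 1:2],
    elbow = fk$elbow + jitter[, 3:4],
    shoulder = matrix(fk$shoulder, n, 2, byrow = TRUE) + jitter[, 5:6],
    fs = cfg$fs_pos, L_sld = profile$upper_arm_m, L_elb = profile$forearm_m)
  emg <- synthesize_trial_emg(traj, profile, cfg,
                              seed = derive_seed(cfg$seed, profile$subject_id,
                                                 trial, 4L),
                              session = session)
  emg$meta$trial <- as.integer(trial)
  list(trajectory = traj, motion = motion, emg = emg,
       meta = list(subject = profile$subject_id, trial = as.integer(trial),
                   session = session,
                   start_angle = mv$start_angle, end_angle = mv$end_angle))
}

#' Generate a full synthetic cohort
#'
#' Produces, for every subject and trial, the raw EMG recording, noisy
#' marker positions (via forward kinematics from the trial's minimum-jerk
#' trajectory) and trial metadata. Deterministic given the config and its
#' seed. Note that a default-sized cohort (10 subjects x 360 trials x 12
#' channels x 4.6 s at 2000 Hz) holds roughly 3 GB of raw samples; use
#' [process_cohort()] with a config argument for memory-lean full-scale
#' runs, and `generate_cohort()` for reduced cohorts and inspection.
#'
#' @param config a [cohort_config()].
#' @return An object of class `emg_cohort`: the config plus one entry per
#'   subject holding the profile and a list of trials.
#' @export
generate_cohort <- function(config) {
  cfg <- validate_cohort_config(config)
  subjects <- lapply(seq_len(cfg$n_subjects), function(s) {
    prof <- subject_profile(s, cfg)
    schedule <- movement_schedule(cfg, s)
    trials <- lapply(seq_len(cfg$n_trials), function(tr) {
      simulate_trial(cfg, prof, tr, schedule)
    })
    list(profile = prof, trials = trials)
  })
  structure(list(config = cfg, subjects = subjects), class = "emg_cohort")
}

#' @export
print.emg_cohort <- function(x, ...) {
  cat(sprintf("<emg_cohort> %d subjects x %d trials x %d channels (seed %d)\n",
              x$config$n_subjects, x$config$n_trials, x$config$n_channels,
              x$config$seed))
  invisible(x)
}
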