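test_that("rest-only EMG sits at the gained noise floor", {
  cfg <- tiny_config(allow_rest_trials = TRUE, trial_spread = 0,
                     session_spread = 0)
  prof <- subject_profile(1, cfg)
  traj <- generate_trajectory(90, 90, cfg, seed = 2)
  rec <- synthesize_trial_emg(traj, prof, cfg, seed = 3)
  # RMS of a modulated band-limited carrier ~ envelope amplitude; skip the
  # filter warm-up
  x <- rec$samples[2001:9200, , drop = FALSE]
  rms <- sqrt(colMeans(x^2))
  expected <- prof$channel_gains * cfg$noise_floor
  expect_equal(unname(rms / expected), rep(1, cfg$n_channels),
               tolerance = 0.05)
})

test_that("flexor channels activate on flexion, extensor channels on extension", {
  cfg <- tiny_config()
  prof <- subject_profile(1, cfg)
  move_rms <- function(start, end) {
    traj <- generate_trajectory(start, end, cfg, seed = 9)
    rec <- synthesize_trial_emg(traj, prof, cfg, seed = 10)
    idx <- which(seq_len(nrow(rec$samples)) / cfg$fs_emg > traj$t_onset &
                   seq_len(nrow(rec$samples)) / cfg$fs_emg < traj$t_offset)
    sqrt(colMeans(rec$samples[idx, , drop = FALSE]^2)) / prof$channel_gains
  }
  flex <- move_rms(30, 120)
  ext <- move_rms(120, 30)
  flexors <- prof$channel_roles == "flexor"
  extensors <- prof$channel_roles == "extensor"
  expect_gt(min(flex[flexors]), max(flex[extensors]))
  expect_gt(min(ext[extensors]), max(ext[flexors]))
})

test_that("carrier power is concentrated in the 20-450 Hz band", {
  cfg <- tiny_config(allow_rest_trials = TRUE)
  prof <- subject_profile(1, cfg)
  traj <- generate_trajectory(90, 90, cfg, seed = 4)
  rec <- synthesize_trial_emg(traj, prof, cfg, seed = 5)
  # periodogram oracle on a long rest segment
  x <- rec$samples[1001:9200, 1]
  p <- Mod(fft(x))^2
  freq <- (seq_along(p) - 1) / length(p) * cfg$fs_emg
  half <- freq <= cfg$fs_emg / 2
  inband <- half & freq >= 20 & freq <= 450
  frac_out <- 1 - sum(p[inband]) / sum(p[half])
  expect_lt(frac_out, 0.05)
})

test_that("cohort generation is deterministic and has the configured shape", {
  cfg <- tiny_config()
  a <- generate_cohort(cfg)
  b <- generate_cohort(cfg)
  expect_identical(a, b)
  expect_length(a$subjects, cfg$n_subjects)
  expect_length(a$subjects[[1]]$trials, cfg$n_trials)
  tr <- a$subjects[[1]]$trials[[1]]
  expect_equal(dim(tr$emg$samples),
               c(round(4.6 * cfg$fs_emg), cfg$n_channels))
  expect_equal(nrow(tr$motion$hand), round(4.6 * cfg$fs_pos))
  # every trial is one of the 12 movements; distinct per-subject gains
  moves <- unique(do.call(rbind, lapply(a$subjects[[1]]$trials, function(t) {
    data.frame(s = t$meta$start_angle, e = t$meta$end_angle)
  })))
  expect_lte(nrow(moves), 12)
  expect_false(identical(a$subjects[[1]]$profile$channel_gains,
                         a$subjects[[2]]$profile$channel_gains))
})

test_that("gain_spread = 0 gives identical channel gains across subjects", {
  cfg <- tiny_config(gain_spread = 0)
  p1 <- subject_profile(1, cfg)
  p2 <- subject_profile(2, cfg)
  expect_equal(p1$channel_gains, rep(1, cfg$n_channels))
  expect_identical(p1$channel_gains, p2$channel_gains)
})

test_that("between-subject RMS heterogeneity grows with gain_spread", {
  spread_distance <- function(gain_spread) {
    cfg <- cohort_config(n_subjects = 4, n_trials = 10, session_size = 10,
                         block_size = 10, seed = 21L,
                         gain_spread = gain_spread, snr_spread = 0,
                         session_spread = 0, trial_spread = 0)
    rms <- sapply(seq_len(cfg$n_subjects), function(s) {
      prof <- subject_profile(s, cfg)
      trial <- emgswn:::simulate_trial(cfg, prof, 1)
      sqrt(colMeans(trial$emg$samples^2))
    })
    d <- dist(t(log(rms)))
    mean(d)
  }
  d0 <- spread_distance(0)
  d1 <- spread_distance(0.3)
  d2 <- spread_distance(0.9)
  expect_lt(d0, d1)
  expect_lt(d1, d2)
})

test_that("labels recovered from generated positions match the trajectory's velocity sign", {
  fix <- one_preprocessed_trial()
  kept <- kept_indices(nrow(fix$pre$samples))
  recovered <- emgswn:::trial_labels(fix$trial$motion, kept)
  truth <- encode_targets(fix$trial$trajectory, kept = kept)
  # agreement away from interval boundaries: allow the few boundary samples
  # where measurement noise flips the dead-band decision
  expect_gt(mean(as.character(recovered) == as.character(truth)), 0.95)
  expect_setequal(levels(recovered), c("rest", "flexion", "extension"))
})

test_that("zero-length trajectories are rejected", {
  cfg <- tiny_config()
  prof <- subject_profile(1, cfg)
  bad <- structure(list(theta_elb = numeric(0), theta_sld = numeric(0),
                        fs = cfg$fs_pos), class = "joint_trajectory")
  expect_error(synthesize_trial_emg(bad, prof, cfg), "zero-length")
})
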