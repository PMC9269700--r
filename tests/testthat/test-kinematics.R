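test_that("inverse kinematics solves the fully extended arm analytically", {
  n <- 3
  mot <- motion_recording(hand = matrix(c(0, 0.55), n, 2, byrow = TRUE),
                          elbow = matrix(c(0, 0.30), n, 2, byrow = TRUE),
                          shoulder = matrix(0, n, 2), fs = 500,
                          L_sld = 0.30, L_elb = 0.25)
  traj <- inverse_kinematics(mot)
  expect_equal(traj$theta_sld, rep(90, n), tolerance = 1e-9)
  expect_equal(traj$theta_elb, rep(0, n), tolerance = 1e-9)
})

test_that("unreachable hand positions raise an error naming the sample", {
  mot <- motion_recording(hand = rbind(c(0, 0.50), c(0, 0.60)),
                          elbow = matrix(0, 2, 2),
                          shoulder = matrix(0, 2, 2), fs = 500,
                          L_sld = 0.30, L_elb = 0.25)
  expect_error(inverse_kinematics(mot), "sample 2")
})

test_that("inverse kinematics inverts forward kinematics over the workspace", {
  set.seed(19)
  n <- 1000
  th_s <- runif(n, -90, 90)
  th_e <- runif(n, 1e-3, 150)
  fk <- forward_kinematics(th_s, th_e, 0.31, 0.26)
  mot <- motion_recording(fk$hand, fk$elbow, matrix(0, n, 2), 500,
                          0.31, 0.26)
  traj <- inverse_kinematics(mot)
  expect_lt(max(abs(traj$theta_sld - th_s)), 1e-6)
  expect_lt(max(abs(traj$theta_elb - th_e)), 1e-6)
})

test_that("forward kinematics geometry: extension, right angle, scaling", {
  fk <- forward_kinematics(90, 0, 0.3, 0.25)
  expect_equal(as.numeric(fk$hand), c(0, 0.55), tolerance = 1e-12)
  # right-angle flexion under the round-trip-consistent convention
  fk2 <- forward_kinematics(90, 90, 0.3, 0.25)
  expect_equal(as.numeric(fk2$hand), c(-0.25, 0.30), tolerance = 1e-12)
  expect_equal(as.numeric(fk2$elbow), c(0, 0.30), tolerance = 1e-12)
  # limb lengths scaled by a scale the positions by a
  fk3 <- forward_kinematics(37, 65, 2 * 0.3, 2 * 0.25)
  expect_equal(fk3$hand, 2 * forward_kinematics(37, 65, 0.3, 0.25)$hand,
               tolerance = 1e-12)
})

test_that("zero-phase smoothing preserves the passband and kills jitter without lag", {
  fs <- 500
  t <- (0:2299) / fs
  clean <- 0.1 + 0.01 * sin(2 * pi * 2 * t)
  jitter <- 0.002 * sin(2 * pi * 100 * t)
  mot <- motion_recording(hand = cbind(clean + jitter, clean),
                          elbow = matrix(0.1, 2300, 2),
                          shoulder = matrix(0, 2300, 2),
                          fs = fs, L_sld = 0.3, L_elb = 0.25)
  sm <- smooth_positions(mot)
  mid <- 301:2000
  # 2 Hz component preserved within 1% (analytic squared 2nd-order
  # Butterworth response at 2/20 Hz is ~0.99995)
  resid2 <- sm$hand[mid, 2] - clean[mid]
  expect_lt(max(abs(resid2)), 0.01 * 0.01)
  # 100 Hz jitter attenuated > 99% (analytic |H|^2 at 100/20 Hz ~ 1.6e-3)
  resid100 <- sm$hand[mid, 1] - sm$hand[mid, 2]
  expect_lt(max(abs(resid100)), 0.01 * max(abs(jitter)))
  # zero lag: cross-correlation of the smoothed passband signal peaks at 0
  cc <- stats::ccf(sm$hand[mid, 2], clean[mid], lag.max = 10, plot = FALSE)
  expect_equal(cc$lag[which.max(cc$acf)], 0)
  # constants pass unchanged
  expect_equal(sm$elbow[mid, 1], rep(0.1, length(mid)), tolerance = 1e-9)
})

test_that("velocity coding thresholds are inclusive at +/-2 deg/s", {
  # fs = 1 keeps the per-sample angle steps exactly representable, so the
  # coded velocity hits the +/-2.0 boundary exactly
  mk <- function(rate_deg_s) {
    structure(list(theta_elb = cumsum(rep(rate_deg_s, 10)),
                   theta_sld = rep(0, 10), fs = 1),
              class = "joint_trajectory")
  }
  expect_true(all(encode_targets(mk(2.0)) == "flexion"))
  expect_true(all(encode_targets(mk(-2.0)) == "extension"))
  expect_true(all(encode_targets(mk(1.99)) == "rest"))
  expect_true(all(encode_targets(mk(-1.99)) == "rest"))
  expect_true(all(encode_targets(mk(0)) == "rest"))
  # 1 degree per sample at 500 Hz = 500 deg/s
  theta <- cumsum(rep(1, 20))
  tr500 <- structure(list(theta_elb = theta, theta_sld = rep(0, 20),
                          fs = 500), class = "joint_trajectory")
  expect_true(all(encode_targets(tr500) == "flexion"))
})

test_that("velocity series replicates its final sample and labels partition", {
  theta <- c(0, 0.1, 0.3, 0.3)
  v <- elbow_velocity(theta, 500)
  expect_length(v, 4)
  expect_equal(v[4], v[3])
  expect_error(elbow_velocity(1, 500), "at least 2")
  set.seed(4)
  traj <- structure(list(theta_elb = cumsum(rnorm(200, 0, 0.01)),
                         theta_sld = rep(0, 200), fs = 500),
                    class = "joint_trajectory")
  lab <- encode_targets(traj)
  expect_false(anyNA(lab))
  expect_length(lab, 200)
})

test_that("labels align row-for-row with features from the same trial", {
  fix <- one_preprocessed_trial()
  fm <- assemble_features(emgswn:::advance_stage(fix$pre, "normalized"),
                          feature_spec("MAV"))
  lab <- emgswn:::trial_labels(fix$trial$motion, attr(fm, "kept"))
  expect_equal(length(lab), nrow(fm))
})
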