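#' Planar two-link forward kinematics
#'
#' Maps shoulder and elbow angles to elbow and hand marker positions for a
#' planar two-link arm. The upper arm points along direction `theta_sld`
#' (degrees from the +x axis) and the forearm along `theta_sld + theta_elb`,
#' so `theta_elb = 0` is the fully extended arm and increasing `theta_elb`
#' is elbow flexion. This convention is the inverse of
#' [inverse_kinematics()]: the round trip reproduces the input angles.
#'
#' @param theta_sld,theta_elb angle vectors in degrees.
#' @param L_sld,L_elb upper-arm and forearm lengths in metres.
#' @param shoulder length-2 shoulder position (metres).
#' @return List with `hand` and `elbow` (n x 2 matrices) and `shoulder`.
#' @export
forward_kinematics <- function(theta_sld, theta_elb, L_sld, L_elb,
                               shoulder = c(0, 0)) {
  stopifnot(length(theta_sld) == length(theta_elb),
            all(is.finite(theta_sld)), all(is.finite(theta_elb)))
  a1 <- theta_sld * pi / 180
  a2 <- (theta_sld + theta_elb) * pi / 180
  elbow <- cbind(shoulder[1] + L_sld * cos(a1),
                 shoulder[2] + L_sld * sin(a1))
  hand <- cbind(elbow[, 1] + L_elb * cos(a2),
                elbow[, 2] + L_elb * sin(a2))
  colnames(elbow) <- colnames(hand) <- c("x", "y")
  list(hand = hand, elbow = elbow, shoulder = shoulder)
}

#' Marker-position recording
#'
#' Container for planar hand/elbow/shoulder marker positions with sampling
#' rate and limb lengths. The elbow marker is carried as metadata only; the
#' joint-angle conversion uses hand and shoulder positions plus limb
#' lengths.
#'
#' @param hand,elbow,shoulder n x 2 matrices of (x, y) positions in metres.
#' @param fs sampling rate in Hz.
#' @param L_sld,L_elb upper-arm and forearm lengths in metres.
#' @return An object of class `motion_recording`.
#' @export
motion_recording <- function(hand, elbow, shoulder, fs, L_sld, L_elb) {
  hand <- as.matrix(hand); elbow <- as.matrix(elbow)
  shoulder <- as.matrix(shoulder)
  stopifnot(ncol(hand) == 2, ncol(shoulder) == 2,
            nrow(hand) == nrow(shoulder))
  stopifnot_scalar_pos(fs, "fs")
  stopifnot_scalar_pos(L_sld, "L_sld")
  stopifnot_scalar_pos(L_elb, "L_elb")
  structure(list(hand = hand, elbow = elbow, shoulder = shoulder, fs = fs,
                 L_sld = L_sld, L_elb = L_elb),
            class = "motion_recording")
}

#' Zero-phase smoothing of marker positions
#'
#' Applies a zero-phase (forward-backward) 2nd-order Butterworth low-pass at
#' 20 Hz to every coordinate, removing measurement jitter without phase lag.
#' Positions, unlike EMG, are processed offline for label generation, so a
#' non-causal filter is appropriate.
#'
#' @param motion a [motion_recording()].
#' @param cutoff_hz low-pass cutoff in Hz.
#' @return The smoothed `motion_recording`.
#' @export
smooth_positions <- function(motion, cutoff_hz = 20) {
  stopifnot(inherits(motion, "motion_recording"))
  n <- nrow(motion$hand)
  if (n < 18) {
    stop("recording too short to smooth (need at least 18 samples)",
         call. = FALSE)
  }
  bf <- signal::butter(2, cutoff_hz / (motion$fs / 2), type = "low")
  # odd-reflection padding suppresses the start/end transients of the
  # forward-backward pass (velocity labels are taken near the trial end)
  pad <- min(50L, n - 1L)
  smooth1 <- function(x) {
    xp <- c(2 * x[1] - x[(pad + 1):2], x,
            2 * x[length(x)] - x[(length(x) - 1):(length(x) - pad)])
    as.numeric(signal::filtfilt(bf, xp))[(pad + 1):(pad + length(x))]
  }
  for (m in c("hand", "elbow", "shoulder")) {
    motion[[m]] <- apply(motion[[m]], 2, smooth1)
  }
  motion
}

#' Planar two-link inverse kinematics
#'
#' Converts hand and shoulder positions to shoulder and elbow joint angles
#' (degrees). With `a = y_hand - y_sld`, `b = x_hand - x_sld`,
#' `c = (a^2+b^2+L_sld^2-L_elb^2) / (2 L_sld)` and
#' `d = (a^2+b^2-L_sld^2+L_elb^2) / (2 L_elb)`:
#' \deqn{\theta_{sld} = atan2d(a, b) - atan2d(\sqrt{a^2+b^2-c^2},\, c)}
#' \deqn{\theta_{elb} = atan2d(\sqrt{a^2+b^2-c^2},\, c) +
#'                      atan2d(\sqrt{a^2+b^2-d^2},\, d)}
#' The elbow angle is measured from full extension; it is the exact inverse
#' of [forward_kinematics()] for elbow angles in (0, 180) degrees.
#'
#' @param motion a [motion_recording()].
#' @return A `joint_trajectory` with `theta_sld` and `theta_elb` in degrees.
#' @export
inverse_kinematics <- function(motion) {
  stopifnot(inherits(motion, "motion_recording"))
  a <- motion$hand[, 2] - motion$shoulder[, 2]
  b <- motion$hand[, 1] - motion$shoulder[, 1]
  r2 <- a^2 + b^2
  Ls <- motion$L_sld; Le <- motion$L_elb
  cc <- (r2 + Ls^2 - Le^2) / (2 * Ls)
  dd <- (r2 - Ls^2 + Le^2) / (2 * Le)
  qc <- r2 - cc^2
  qd <- r2 - dd^2
  # tolerate tiny negative radicands from floating-point at full extension
  tol <- -1e-9 * max(1, Ls + Le)^2
  bad <- which(qc < tol | qd < tol |
                 sqrt(r2) > Ls + Le + 1e-9 | sqrt(r2) < abs(Ls - Le) - 1e-9)
  if (length(bad)) {
    stop(sprintf("hand position unreachable at sample %d (|hand-shoulder| = %.4f m, limbs %.3f + %.3f m)",
                 bad[1], sqrt(r2[bad[1]]), Ls, Le), call. = FALSE)
  }
  qc <- pmax(qc, 0); qd <- pmax(qd, 0)
  atan2d <- function(y, x) atan2(y, x) * 180 / pi
  alpha <- atan2d(sqrt(qc), cc)
  structure(list(
    theta_sld = atan2d(a, b) - alpha,
    theta_elb = alpha + atan2d(sqrt(qd), dd),
    fs = motion$fs
  ), class = "joint_trajectory")
}

#' Elbow angular velocity by forward differences
#'
#' `v_t = (theta_{t+1} - theta_t) * fs` in deg/s; the final sample, where
#' the forward difference is undefined, replicates its predecessor so the
#' velocity series has the same length as the angle series.
#'
#' @param theta_elb elbow angle in degrees.
#' @param fs sampling rate in Hz.
#' @return Numeric vector of angular velocities in deg/s.
#' @export
elbow_velocity <- function(theta_elb, fs) {
  n <- length(theta_elb)
  if (n < 2) stop("need at least 2 angle samples", call. = FALSE)
  v <- diff(theta_elb) * fs
  c(v, v[n - 1])
}

#' Encode rest/flexion/extension targets from a joint trajectory
#'
#' Codes each sample from the elbow angular velocity with a +/-2 deg/s dead
#' band: flexion if `v >= 2`, extension if `v <= -2`, rest otherwise
#' (boundaries inclusive). Optionally subsamples to the feature timestamps
#' via `kept` (the same trim + stride-25 rule as feature extraction) so
#' labels and features align row-for-row.
#'
#' @param trajectory a `joint_trajectory`.
#' @param kept optional integer vector of sample indices to keep (see
#'   [kept_indices()]).
#' @param threshold dead-band half-width in deg/s.
#' @return Factor with levels `rest`, `flexion`, `extension`.
#' @export
encode_targets <- function(trajectory, kept = NULL, threshold = 2.0) {
  stopifnot(inherits(trajectory, "joint_trajectory"))
  v <- elbow_velocity(trajectory$theta_elb, trajectory$fs)
  lab <- rep("rest", length(v))
  lab[v >= threshold] <- "flexion"
  lab[v <= -threshold] <- "extension"
  lab <- factor(lab, levels = c("rest", "flexion", "extension"))
  if (!is.null(kept)) lab <- lab[kept]
  lab
}
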