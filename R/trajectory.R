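#' Generate a minimum-jerk elbow trajectory for one trial
#'
#' The elbow angle is constant at `start_angle` during pre-rest, follows a
#' minimum-jerk (quintic) profile from `start_angle` to `end_angle` over a
#' movement window drawn inside the task period, and stays at `end_angle`
#' afterwards. The shoulder angle is constant. Minimum-jerk boundary
#' conditions make angular velocity and acceleration zero at both movement
#' endpoints.
#'
#' The movement duration is drawn uniformly from
#' `config$move_duration_range` and the onset uniformly so the movement
#' finishes within the task period, matching the task rule that movements
#' complete between 0 and `task_s` seconds after the go cue.
#'
#' @param start_angle,end_angle elbow angles in degrees; both must belong to
#'   `config$target_angles`. Equal angles are rejected unless
#'   `config$allow_rest_trials` is set.
#' @param config a [cohort_config()].
#' @param seed integer seed for the movement timing draw.
#' @return An object of class `joint_trajectory` with fields `theta_sld`,
#'   `theta_elb` (degrees, length `n`), `fs`, movement timing, and target
#'   metadata.
#' @export
generate_trajectory <- function(start_angle, end_angle, config, seed = 1L) {
  cfg <- config
  if (!(start_angle %in% cfg$target_angles) ||
      !(end_angle %in% cfg$target_angles)) {
    stop("start and end angles must belong to `config$target_angles`",
         call. = FALSE)
  }
  if (start_angle == end_angle && !cfg$allow_rest_trials) {
    stop("pure-rest trials (start == end) are disabled; the task set is the ",
         "12 movements between distinct targets", call. = FALSE)
  }
  fs <- cfg$fs_pos
  n <- round(trial_duration(cfg) * fs)
  timing <- with_seed(seed, {
    dur <- runif(1, cfg$move_duration_range[1], cfg$move_duration_range[2])
    onset_in_task <- runif(1, 0, cfg$task_s - dur)
    c(dur = dur, onset = cfg$pre_rest_s + onset_in_task)
  })
  t <- (seq_len(n) - 1) / fs
  tau <- (t - timing[["onset"]]) / timing[["dur"]]
  tau <- pmin(pmax(tau, 0), 1)
  theta <- start_angle +
    (end_angle - start_angle) * (10 * tau^3 - 15 * tau^4 + 6 * tau^5)
  structure(list(
    theta_sld = rep(cfg$shoulder_angle_deg, n),
    theta_elb = theta,
    fs = fs,
    t_onset = timing[["onset"]],
    t_offset = timing[["onset"]] + timing[["dur"]],
    duration = timing[["dur"]],
    start_angle = start_angle,
    end_angle = end_angle
  ), class = "joint_trajectory")
}

#' @export
print.joint_trajectory <- function(x, ...) {
  cat(sprintf("<joint_trajectory> %d samples @ %g Hz, elbow %g -> %g deg",
              length(x$theta_elb), x$fs,
              x$theta_elb[1], x$theta_elb[length(x$theta_elb)]))
  if (!is.null(x$t_onset)) {
    cat(sprintf(" (movement %.2f-%.2f s)", x$t_onset, x$t_offset))
  }
  cat("\n")
  invisible(x)
}
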