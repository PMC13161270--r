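#' Pseudorandom target schedule
#'
#' Targets sit at `n_targets` equally spaced angles on the target ring and are
#' pseudorandomized so that every consecutive set of `n_targets` trials visits
#' each target exactly once (a "cycle"). A trailing partial cycle draws from a
#' fresh permutation.
#'
#' @param n_trials number of trials to schedule.
#' @param n_targets number of equally spaced targets (default 8).
#' @return numeric vector of target angles in degrees (math convention:
#'   0 = +x axis, counter-clockwise positive).
#' @export
target_schedule <- function(n_trials, n_targets = 8L) {
  angles <- seq(0, 360, length.out = n_targets + 1L)[seq_len(n_targets)]
  n_cycles <- ceiling(n_trials / n_targets)
  out <- unlist(lapply(seq_len(n_cycles), function(i) angles[sample.int(n_targets)]))
  out[seq_len(n_trials)]
}

#' Simulate a single-rate state-space learner
#'
#' The intended reach direction (relative to the target) evolves as a single
#' adaptive state `x`. On feedback trials the state moves a fraction
#' `learning_rate` of the remaining error toward the rotation magnitude `r`
#' (`x <- x + B (r - x)`); on no-feedback (Retention) trials the state decays
#' by `retention_factor`. Baseline and Washout are feedback trials with
#' `r = 0`. The intended angle on a trial is the state *before* that trial's
#' update, starting from 0.
#'
#' @param config a [cohort_config()].
#' @return tibble with `trial_index`, `condition`, `cycle_index` and
#'   `intended_deg`, ordered Baseline, Adaptation, Retention, Washout.
#' @export
simulate_learner <- function(config) {
  stopifnot(inherits(config, "cohort_config"))
  tc <- config$n_trials_per_condition[task_conditions()]
  condition <- rep(names(tc), times = tc)
  n <- length(condition)
  intended <- numeric(n)
  x <- 0
  B <- config$learning_rate
  rho <- config$retention_factor
  for (i in seq_len(n)) {
    intended[i] <- x
    x <- switch(condition[i],
                baseline = ,
                washout = x + B * (0 - x),
                adaptation = x + B * (abs(config$rotation_deg) - x),
                retention = rho * x)
  }
  within_cond <- unlist(lapply(tc, seq_len), use.names = FALSE)
  tibble::tibble(
    trial_index = seq_len(n),
    condition = condition,
    trial_in_condition = within_cond,
    cycle_index = (within_cond - 1L) %/% config$n_targets + 1L,
    intended_deg = intended)
}

minjerk <- function(tau) {
  tau <- pmin(pmax(tau, 0), 1)
  10 * tau^3 - 15 * tau^4 + 6 * tau^5
}

#' Simulate one reach trajectory
#'
#' Builds a minimum-jerk radial reach. Under a counter-clockwise cursor
#' rotation, compensation means aiming the hand clockwise of the target, so
#' the hand direction is `target_angle - intended_angle` plus Gaussian motor
#' noise. Onset latency is drawn from the lognormal response-time model (with
#' its additive stage/condition shifts) and peak speed from the velocity
#' model; the reach extends ~10% beyond the target ring so that ring-crossing
#' measures interpolate between interior samples. A hold period at the start
#' position produces the duplicated frames the cleaning cascade removes.
#'
#' Randomness is taken from R's global RNG stream: calls are deterministic
#' given the RNG state (seed the stream, or call via [simulate_cohort()]).
#'
#' @param intended_angle learner state for the trial, degrees.
#' @param target_angle target direction, degrees.
#' @param config a [cohort_config()].
#' @param early logical: is the trial in its condition's early (first-8) window?
#' @param condition task condition label.
#' @param subject_rt_shift,subject_v_shift participant-level intercepts
#'   (seconds, mm/s).
#' @param subject_theta_shift participant-level reach-direction bias
#'   (degrees, in the reported hand-angle convention).
#' @return object of class `trajectory`: list with `t` (s), `x`, `y` (mm),
#'   `cue_time`, `target_deg`, `condition`, `timeout_flag`.
#' @export
simulate_trajectory <- function(intended_angle, target_angle, config,
                                early = FALSE, condition = "baseline",
                                subject_rt_shift = 0, subject_v_shift = 0,
                                subject_theta_shift = 0) {
  rp <- config$rt_params
  latency <- stats::rlnorm(1, rp$meanlog, rp$sdlog) + subject_rt_shift +
    (if (early) rp$early_shift else 0) +
    (if (condition == "adaptation") rp$adaptation_shift else 0)
  latency <- max(latency, 0.05)
  vp <- config$velocity_params
  v_peak <- stats::rnorm(1, vp$mean, vp$sd) + subject_v_shift +
    (if (condition == "retention") vp$retention_shift else 0)
  v_peak <- max(v_peak, 100)
  theta <- target_angle - intended_angle - subject_theta_shift +
    stats::rnorm(1, 0, config$motor_noise_sd)

  path_len <- 1.1 * config$target_radius_mm
  dur <- 1.875 * path_len / v_peak        # minimum-jerk peak speed = 1.875 D/T
  dt <- 1 / config$sample_rate
  t <- seq(0, latency + dur + 3 * dt, by = dt)
  s <- path_len * minjerk((t - latency) / dur)
  rad <- theta * pi / 180
  # time from movement onset to crossing the target ring (analytic profile)
  tau_cross <- stats::uniroot(function(u) minjerk(u) - config$target_radius_mm / path_len,
                              c(0, 1))$root
  structure(list(
    t = t, x = s * cos(rad), y = s * sin(rad),
    cue_time = 0, target_deg = target_angle, condition = condition,
    timeout_flag = (tau_cross * dur) > 0.300),
    class = "trajectory")
}

#' @export
print.trajectory <- function(x, ...) {
  cat(sprintf("<trajectory> %d samples, %.2f s, target %g deg, %s%s\n",
              length(x$t), max(x$t), x$target_deg, x$condition,
              if (isTRUE(x$timeout_flag)) " [timeout]" else ""))
  invisible(x)
}
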