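#' Simulate the participant roster
#'
#' Draws demographics (age, Edinburgh Handedness Inventory) and State-Trait
#' Anxiety Inventory scores from the per-group normal distributions in the
#' configuration. EHI scores are truncated to [-100, 100].
#'
#' @param config a [cohort_config()].
#' @return tibble with `participant`, `group`, `age`, `ehi`, `stai_state`,
#'   `stai_trait`.
#' @export
simulate_participants <- function(config) {
  n <- config$n_anxiety + config$n_control
  group <- rep(c("anxiety", "control"), c(config$n_anxiety, config$n_control))
  draw <- function(par_by_group) {
    vapply(group, function(g) {
      p <- par_by_group[[g]]
      stats::rnorm(1, p[1], p[2])
    }, numeric(1), USE.NAMES = FALSE)
  }
  tibble::tibble(
    participant = sprintf("S%02d", seq_len(n)),
    group = group,
    age = round(draw(config$demo_params$age), 1),
    ehi = pmin(pmax(draw(config$demo_params$ehi), -100), 100),
    stai_state = draw(config$stai_params$state),
    stai_trait = draw(config$stai_params$trait))
}

tlx_dimensions <- function() {
  c("mental", "physical", "temporal", "performance", "effort", "frustration")
}

#' Simulate NASA-TLX responses for one participant
#'
#' Independent truncated (and rounded) normals per dimension on the 21-point
#' 0-20 scale; only an Adaptation elevation is injected by default, matching
#' the null group findings the design assumes.
#'
#' @param config a [cohort_config()].
#' @param participant participant id.
#' @param subject_shift participant-level workload intercept (scale points),
#'   shared across dimensions and conditions.
#' @return tibble, one row per condition (baseline, adaptation, retention),
#'   with the six dimension scores.
#' @export
simulate_tlx <- function(config, participant = "S01", subject_shift = 0) {
  tp <- config$tlx_params
  conds <- c("baseline", "adaptation", "retention")
  rows <- lapply(conds, function(cond) {
    mu <- tp$mean + subject_shift +
      if (cond == "adaptation") tp$adaptation_shift else 0
    val <- round(pmin(pmax(stats::rnorm(6, mu, tp$sd), 0), 20))
    stats::setNames(as.list(val), tlx_dimensions())
  })
  out <- dplyr::bind_rows(rows)
  dplyr::bind_cols(tibble::tibble(participant = participant, condition = conds), out)
}

#' Simulate a full study cohort
#'
#' Generates, per participant: the learner's intended-angle sequence over the
#' Baseline / Adaptation / Retention / Washout schedule, a pseudorandom target
#' schedule, reach trajectories, movement-locked EEG epochs for the Adaptation
#' and Retention conditions (the only conditions the EEG analysis uses), and
#' NASA-TLX responses. Everything is drawn from a single RNG stream seeded
#' with `config$seed`, so an identical config reproduces the bundle exactly.
#'
#' @param config a [cohort_config()].
#' @param what character subset of `c("behavior", "eeg", "tlx")`; skipping a
#'   component skips its random draws (useful for replicate simulations that
#'   only need one data stream).
#' @return object of class `cohort_bundle`: list with `config`,
#'   `participants`, `trials` (per-trial metadata incl. `intended_deg`),
#'   `trajectories` (per-participant list of `trajectory` objects), `epochs`
#'   (named `"<participant>.<condition>"` list of [epoch_set()]s), `tlx`.
#' @export
simulate_cohort <- function(config,
                            what = c("behavior", "eeg", "tlx")) {
  stopifnot(inherits(config, "cohort_config"))
  what <- match.arg(what, several.ok = TRUE)
  set.seed(config$seed)
  participants <- simulate_participants(config)

  trials_list <- list()
  trajectories <- list()
  epochs <- list()
  tlx_list <- list()

  for (i in seq_len(nrow(participants))) {
    pid <- participants$participant[i]
    grp <- participants$group[i]
    sched <- simulate_learner(config)
    sched$participant <- pid
    sched$target_deg <- unlist(lapply(
      config$n_trials_per_condition[task_conditions()],
      function(nt) target_schedule(nt, config$n_targets)), use.names = FALSE)

    if ("behavior" %in% what) {
      rt_shift <- stats::rnorm(1, 0, config$rt_params$subject_sd)
      v_shift <- stats::rnorm(1, 0, config$velocity_params$subject_sd)
      theta_shift <- stats::rnorm(1, 0, config$motor_bias_sd)
      trajs <- vector("list", nrow(sched))
      for (k in seq_len(nrow(sched))) {
        cond <- sched$condition[k]
        early <- sched$trial_in_condition[k] <= config$n_targets
        trajs[[k]] <- simulate_trajectory(
          sched$intended_deg[k], sched$target_deg[k], config,
          early = early, condition = cond,
          subject_rt_shift = rt_shift, subject_v_shift = v_shift,
          subject_theta_shift = theta_shift)
        trajs[[k]]$trial_index <- sched$trial_index[k]
      }
      trajectories[[pid]] <- trajs
      sched$timeout_flag <- vapply(trajs, function(tr) tr$timeout_flag, logical(1))
    }

    if ("eeg" %in% what) {
      subj_amp <- stats::rnorm(1, 0, config$mrp_params$subject_sd)
      for (cond in c("adaptation", "retention")) {
        ep <- simulate_epochs(config, grp, cond,
                              config$n_trials_per_condition[[cond]],
                              subject_shift = subj_amp)
        ep$participant <- pid
        epochs[[paste(pid, cond, sep = ".")]] <- ep
      }
    }

    if ("tlx" %in% what)
      tlx_list[[pid]] <- simulate_tlx(
        config, pid,
        subject_shift = stats::rnorm(1, 0, config$tlx_params$subject_sd))
    trials_list[[pid]] <- sched
  }

  structure(list(
    config = config,
    participants = participants,
    trials = dplyr::bind_rows(trials_list),
    trajectories = trajectories,
    epochs = epochs,
    tlx = if (length(tlx_list)) dplyr::bind_rows(tlx_list) else NULL),
    class = "cohort_bundle")
}

#' @export
print.cohort_bundle <- function(x, ...) {
  cat("<cohort_bundle>\n")
  cat(sprintf("  %d participants (%d anxiety / %d control)\n",
              nrow(x$participants),
              sum(x$participants$group == "anxiety"),
              sum(x$participants$group == "control")))
  cat(sprintf("  %d trials total; %d trajectory sets; %d epoch sets; tlx: %s\n",
              nrow(x$trials), length(x$trajectories), length(x$epochs),
              if (is.null(x$tlx)) "none" else paste(nrow(x$tlx), "rows")))
  invisible(x)
}
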