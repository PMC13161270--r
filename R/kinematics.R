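#' Response time of a reach
#'
#' Time between the go cue and the hand's first sample at least `threshold_mm`
#' (Euclidean) from the start position. If the threshold is never crossed the
#' trial is flagged missing (`NA`), not an error.
#'
#' @param traj a `trajectory`.
#' @param threshold_mm movement-detection radius in mm (default 10).
#' @return seconds (non-negative), or `NA_real_`.
#' @export
response_time <- function(traj, threshold_mm = 10) {
  d <- sqrt(traj$x^2 + traj$y^2)
  hit <- which(d >= threshold_mm)
  if (!length(hit)) return(NA_real_)
  traj$t[hit[1]] - traj$cue_time
}

#' Clean trajectory samples
#'
#' Two-step sample cleaning: (1) collapse runs of consecutive samples with
#' identical (x, y) position ("frozen frames") to their first sample; (2) drop
#' samples whose successive-difference magnitude exceeds `iqr_mult` times the
#' interquartile range of all successive-difference magnitudes. When the IQR
#' is zero (all successive steps identical) nothing is removed: a zero-spread
#' step distribution has no outliers.
#'
#' @param traj a `trajectory` with at least 4 samples.
#' @param iqr_mult outlier multiplier (default 10).
#' @return the cleaned `trajectory`, with attributes `n_removed_duplicates`,
#'   `n_removed_iqr` and `unusable` (TRUE when fewer than 4 samples survive).
#' @export
clean_samples <- function(traj, iqr_mult = 10) {
  stopifnot(length(traj$t) >= 4)
  dup <- c(FALSE, diff(traj$x) == 0 & diff(traj$y) == 0)
  n_dup <- sum(dup)
  keep <- !dup
  t <- traj$t[keep]; x <- traj$x[keep]; y <- traj$y[keep]

  n_iqr <- 0L
  if (length(t) >= 2) {
    step <- sqrt(diff(x)^2 + diff(y)^2)
    iqr <- stats::IQR(step)
    # a zero-spread step distribution has no outliers; treat float-level
    # spread (perfectly regular sampling) as zero too
    if (iqr > 1e-10 * max(step)) {
      bad <- c(FALSE, step > iqr_mult * iqr)   # drop the later sample of a jump
      n_iqr <- sum(bad)
      t <- t[!bad]; x <- x[!bad]; y <- y[!bad]
    }
  }
  out <- traj
  out$t <- t; out$x <- x; out$y <- y
  attr(out, "n_removed_duplicates") <- n_dup
  attr(out, "n_removed_iqr") <- n_iqr
  attr(out, "unusable") <- length(t) < 4
  out
}

#' Peak hand speed
#'
#' Maximum of `sqrt(vx^2 + vy^2)` where vx, vy are finite-difference
#' derivatives of position with respect to time over the (cleaned) samples.
#'
#' @param traj a cleaned `trajectory` with at least 2 samples.
#' @return mm/s, or `NA_real_` for an unusable trial.
#' @export
peak_velocity <- function(traj) {
  if (isTRUE(attr(traj, "unusable")) || length(traj$t) < 2) return(NA_real_)
  dt <- diff(traj$t)
  speed <- sqrt(diff(traj$x)^2 + diff(traj$y)^2) / dt
  max(speed)
}

#' Clean a participant's peak-velocity values
#'
#' Left-to-right cascade: values above the absolute cutoff are removed first;
#' then, among the survivors, values deviating more than `sd_mult` standard
#' deviations from the survivors' mean are removed in a single pass (the
#' mean/SD are not re-estimated after removal). With zero spread nothing is
#' removed (a deviation of 0 is not greater than 0).
#'
#' @param values numeric vector of per-trial peak velocities (mm/s); `NA`s are
#'   counted as already-missing and passed through.
#' @param abs_cutoff absolute cutoff in mm/s (default 2000).
#' @param sd_mult SD multiplier (default 3).
#' @return list with `values` (input length, cleaned values with removals set
#'   to `NA`), `keep` (logical), and `report`: a one-row tibble with
#'   `n_input`, `n_removed_absolute`, `n_removed_3sd`, `n_retained`,
#'   `retained_fraction` (= retained / input, exactly) and `all_removed`.
#' @export
clean_peak_velocity <- function(values, abs_cutoff = 2000, sd_mult = 3) {
  finite <- is.finite(values)
  stopifnot(sum(finite) >= 2)
  keep <- finite & values <= abs_cutoff
  n_abs <- sum(finite) - sum(keep)
  m <- mean(values[keep]); s <- stats::sd(values[keep])
  if (is.na(s)) s <- 0
  keep2 <- keep & abs(values - m) <= sd_mult * s
  n_sd <- sum(keep) - sum(keep2, na.rm = TRUE)
  keep2[!finite] <- FALSE
  out <- values
  out[!keep2] <- NA_real_
  n_in <- length(values)
  report <- tibble::tibble(
    n_input = n_in,
    n_removed_absolute = n_abs,
    n_removed_3sd = n_sd,
    n_retained = sum(keep2),
    retained_fraction = sum(keep2) / n_in,
    all_removed = sum(keep2) == 0L)
  if (report$all_removed)
    warning("all peak-velocity values removed for this participant")
  list(values = out, keep = keep2, report = report)
}

#' Trial-wise hand angle (hand theta)
#'
#' Angular deviation of the hand path from the target direction, computed from
#' movement onset (the earliest sample at which either coordinate deviates
#' from the previous sample by more than `onset_tol`) to the endpoint, wrapped
#' into (-180, 180] by circular subtraction. The sign convention fixes
#' compensation of a counter-clockwise cursor rotation as positive: with
#' `rotation_deg > 0` the reported angle is the *clockwise* deviation of the
#' hand from the target, so full compensation of a 45 degree CCW rotation
#' yields +45. With `rotation_deg <= 0` the raw circular difference
#' (hand - target, CCW positive) is returned.
#'
#' @param traj a (cleaned) `trajectory`.
#' @param target_angle target direction in degrees.
#' @param rotation_deg the experiment's cursor rotation (CCW positive);
#'   determines the sign convention, not the geometry.
#' @param onset_tol per-coordinate movement-onset tolerance in mm (default 0,
#'   the literal "deviated from the previous sample"; 0.5 is a noise-robust
#'   alternative).
#' @param endpoint `"ring"` (default): linear interpolation of the crossing of
#'   the target-ring radius, falling back to the last sample if the ring is
#'   never reached; `"last"`: the final sample.
#' @param ring_radius_mm target ring radius for `endpoint = "ring"`.
#' @return degrees in (-180, 180], or `NA_real_` for a degenerate
#'   (zero-length) movement.
#' @export
hand_theta <- function(traj, target_angle, rotation_deg = 45,
                       onset_tol = 0, endpoint = c("ring", "last"),
                       ring_radius_mm = 80) {
  endpoint <- match.arg(endpoint)
  x <- traj$x; y <- traj$y
  if (length(x) < 2) return(NA_real_)
  moved <- which(abs(diff(x)) > onset_tol | abs(diff(y)) > onset_tol)
  if (!length(moved)) return(NA_real_)
  o <- moved[1]                         # onset = last pre-movement sample
  x0 <- x[o]; y0 <- y[o]

  xe <- x[length(x)]; ye <- y[length(y)]
  if (endpoint == "ring") {
    r <- sqrt((x - x0)^2 + (y - y0)^2)
    cross <- which(r >= ring_radius_mm)
    if (length(cross)) {
      j <- cross[1]
      if (j > 1 && r[j] > r[j - 1]) {
        w <- (ring_radius_mm - r[j - 1]) / (r[j] - r[j - 1])
        xe <- x[j - 1] + w * (x[j] - x[j - 1])
        ye <- y[j - 1] + w * (y[j] - y[j - 1])
      } else { xe <- x[j]; ye <- y[j] }
    }
  }
  if (xe == x0 && ye == y0) return(NA_real_)
  hand_dir <- atan2(ye - y0, xe - x0) * 180 / pi
  raw <- wrap_angle(hand_dir - target_angle)
  if (rotation_deg > 0) wrap_angle(-raw) else raw
}

#' Early/late stage summaries
#'
#' Per participant x condition x stage mean of a measure, where stage is
#' defined positionally by original trial index within the condition: the
#' first 8 trials are "early", the last 8 "late", everything else "middle".
#' Removed (NA) trials are excluded from the mean but do not shift the
#' positional windows. Conditions with fewer than 16 trials would have
#' overlapping windows: these are flagged with a warning and the overlapping
#' trials are assigned to "early".
#'
#' @param table a trial table with `participant`, `condition`,
#'   `trial_in_condition` and the measure column.
#' @param measure name of the measure column.
#' @param n_stage_trials trials per stage window (default 8).
#' @return tibble with `participant`, `condition`, `stage`, `mean`, `n_used`.
#' @export
stage_summary <- function(table, measure, n_stage_trials = 8L) {
  stopifnot(measure %in% names(table))
  lab <- stage_labels(table, n_stage_trials)
  tab <- table
  tab$stage <- lab
  tab$.value <- tab[[measure]]
  out <- dplyr::summarise(
    dplyr::group_by(dplyr::filter(tab, stage != "middle"),
                    participant, condition, stage),
    mean = mean(.value, na.rm = TRUE),
    n_used = sum(!is.na(.value)), .groups = "drop")
  out$mean[is.nan(out$mean)] <- NA_real_
  out
}

stage_labels <- function(table, n_stage_trials = 8L) {
  lab <- rep("middle", nrow(table))
  key <- paste(table$participant, table$condition)
  for (k in unique(key)) {
    idx <- which(key == k)
    ord <- idx[order(table$trial_in_condition[idx])]
    n <- length(ord)
    if (n < 2 * n_stage_trials)
      warning("condition with ", n, " trials: early/late windows overlap; ",
              "overlapping trials assigned to early", call. = FALSE)
    early <- ord[seq_len(min(n_stage_trials, n))]
    late <- ord[ord %in% utils::tail(ord, n_stage_trials)]
    lab[late] <- "late"
    lab[early] <- "early"            # early wins on overlap
  }
  lab
}

#' Build the tidy per-trial behavioral table
#'
#' Runs the full kinematic cascade over a cohort's trajectories: sample
#' cleaning, response time, peak velocity, per-participant peak-velocity
#' cleaning, and circular hand angle; labels stages positionally.
#'
#' @param cohort a `cohort_bundle` with trajectories.
#' @param rt_threshold_mm,iqr_mult,pv_abs_cutoff,pv_sd_mult,onset_tol cleaning
#'   thresholds (defaults 10 mm, 10, 2000 mm/s, 3, 0 mm).
#' @return list with `trial_table` (one row per trial: ids, condition, stage,
#'   cycle, `response_time`, `peak_velocity` — `NA` when removed —
#'   `hand_theta`, `removed_reason`) and `cleaning_report` (one row per
#'   participant, including the sample-level removal counts and the exact
#'   `retained_fraction`).
#' @export
build_trial_table <- function(cohort, rt_threshold_mm = 10, iqr_mult = 10,
                              pv_abs_cutoff = 2000, pv_sd_mult = 3,
                              onset_tol = 0) {
  stopifnot(inherits(cohort, "cohort_bundle"), length(cohort$trajectories) > 0)
  cfg <- cohort$config
  rows <- list()
  reports <- list()
  for (pid in names(cohort$trajectories)) {
    trs <- cohort$trajectories[[pid]]
    meta <- cohort$trials[cohort$trials$participant == pid, ]
    meta <- meta[order(meta$trial_index), ]
    n_dup <- 0L; n_iqr <- 0L
    rt <- pv <- th <- rep(NA_real_, length(trs))
    unusable <- logical(length(trs))
    for (k in seq_along(trs)) {
      cl <- clean_samples(trs[[k]], iqr_mult = iqr_mult)
      n_dup <- n_dup + attr(cl, "n_removed_duplicates")
      n_iqr <- n_iqr + attr(cl, "n_removed_iqr")
      unusable[k] <- isTRUE(attr(cl, "unusable"))
      rt[k] <- response_time(trs[[k]], threshold_mm = rt_threshold_mm)
      if (!unusable[k]) {
        pv[k] <- peak_velocity(cl)
        th[k] <- hand_theta(cl, meta$target_deg[k],
                            rotation_deg = cfg$rotation_deg,
                            onset_tol = onset_tol,
                            ring_radius_mm = cfg$target_radius_mm)
      }
    }
    pvc <- clean_peak_velocity(pv, abs_cutoff = pv_abs_cutoff,
                               sd_mult = pv_sd_mult)
    reason <- rep(NA_character_, length(trs))
    reason[unusable] <- "unusable_samples"
    reason[!unusable & !pvc$keep & !is.na(pv)] <- "peak_velocity"
    rows[[pid]] <- tibble::tibble(
      participant = pid,
      trial_index = meta$trial_index,
      condition = meta$condition,
      trial_in_condition = meta$trial_in_condition,
      cycle_index = meta$cycle_index,
      target_deg = meta$target_deg,
      response_time = rt,
      peak_velocity = pvc$values,
      hand_theta = th,
      removed_reason = reason)
    reports[[pid]] <- dplyr::bind_cols(
      tibble::tibble(participant = pid,
                     n_input_trials = length(trs),
                     n_removed_duplicates = n_dup,
                     n_removed_iqr_samples = n_iqr),
      pvc$report[, c("n_removed_absolute", "n_removed_3sd",
                     "n_retained", "retained_fraction")])
  }
  tt <- dplyr::bind_rows(rows)
  tt$stage <- stage_labels(tt)
  list(trial_table = tt, cleaning_report = dplyr::bind_rows(reports))
}

utils::globalVariables(c("participant", "condition", "stage", ".value"))
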