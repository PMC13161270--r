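#' Build a cohort configuration
#'
#' A `cohort_config` bundles every parameter of the synthetic cohort: group
#' sizes, the trial schedule per task condition, the state-space learner, reach
#' kinematics, the movement-readiness-potential (MRP) waveform templates, EEG
#' noise, and questionnaire score distributions. The defaults describe a
#' 31-participant visuomotor rotation study (13 with anxiety disorders, 18
#' controls) with a 45 degree counter-clockwise cursor rotation, endpoint-only
#' feedback, 8 radial targets on an 8 cm ring, and 600 trials split
#' 100/200/200/100 over Baseline, Adaptation, Retention and Washout.
#'
#' @param n_anxiety,n_control participants per group.
#' @param seed integer seed; an identical config (including seed) reproduces a
#'   cohort byte-for-byte.
#' @param rotation_deg cursor rotation in degrees, counter-clockwise positive.
#' @param n_trials_per_condition named counts for
#'   `baseline`, `adaptation`, `retention`, `washout`.
#' @param learning_rate single-rate state-space learning rate, in (0, 1).
#' @param retention_factor per-trial state retention on no-feedback trials,
#'   in (0, 1]; 1 reproduces flat retention.
#' @param motor_noise_sd SD (degrees) of trial-level directional motor noise.
#' @param motor_bias_sd SD (degrees) of a constant participant-level reach
#'   direction bias (between-subject variance of hand angle).
#' @param rt_params lognormal onset-latency parameters `meanlog`, `sdlog`
#'   (seconds) plus additive `early_shift` (applied to the first 8 trials of a
#'   condition), `adaptation_shift` (applied in Adaptation) and a
#'   between-subject `subject_sd`.
#' @param velocity_params peak-speed `mean`/`sd` in mm/s, additive
#'   `retention_shift` and between-subject `subject_sd`.
#' @param mrp_params template amplitudes `rp`, `ns`, `mp` (microvolts,
#'   negative), anxiety-group attenuation deltas `rp_delta`, `ns_delta`,
#'   `mp_delta` (positive microvolts, added to the anxiety template inside the
#'   NS / MP windows only), stage and condition shifts `ns_early_shift`,
#'   `mp_retention_shift`, and a between-subject amplitude `subject_sd`.
#' @param noise_params per-sample SDs (microvolts) of the `broadband_sd` white
#'   and `pink_sd` 1/f noise components.
#' @param artifact_rate per-trial probability of a large-amplitude transient.
#' @param artifact_amp amplitude (microvolts) of the simulated transient.
#' @param sample_rate sampling rate in Hz for both tablet and EEG streams.
#' @param epoch_window epoch extent in ms relative to movement onset.
#' @param channels simulated montage (10-20 labels). Note the montage carries
#'   FC3 rather than FC1, mirroring the acquisition montage.
#' @param roi_channels channels that carry the MRP template.
#' @param target_radius_mm radial target distance in mm.
#' @param n_targets number of equally spaced radial targets.
#' @param stai_params group mean/SD pairs for state and trait STAI scores.
#' @param demo_params group mean/SD pairs for age and handedness (EHI).
#' @param tlx_params NASA-TLX dimension `mean`/`sd` on the 21-point (0-20)
#'   scale plus the Adaptation `adaptation_shift` elevation.
#'
#' @return a validated list of class `cohort_config`.
#' @export
cohort_config <- function(n_anxiety = 13L,
                          n_control = 18L,
                          seed = 1L,
                          rotation_deg = 45,
                          n_trials_per_condition = c(baseline = 100L,
                                                     adaptation = 200L,
                                                     retention = 200L,
                                                     washout = 100L),
                          learning_rate = 0.08,
                          retention_factor = 1,
                          motor_noise_sd = 4,
                          motor_bias_sd = 2,
                          rt_params = list(meanlog = log(0.35), sdlog = 0.25,
                                           early_shift = 0.073,
                                           adaptation_shift = 0.072,
                                           subject_sd = 0.05),
                          velocity_params = list(mean = 600, sd = 100,
                                                 retention_shift = -50.4,
                                                 subject_sd = 40),
                          mrp_params = list(rp = -2, ns = -5, mp = -8,
                                            rp_delta = 0,
                                            ns_delta = 0.883,
                                            mp_delta = 1.289,
                                            ns_early_shift = 0.423,
                                            mp_retention_shift = 0.598,
                                            subject_sd = 1.1),
                          noise_params = list(broadband_sd = 2, pink_sd = 5),
                          artifact_rate = 0.05,
                          artifact_amp = 150,
                          sample_rate = 250,
                          epoch_window = c(-2000, 500),
                          channels = c("F3", "Fz", "FC3", "C3", "Cz",
                                       "F4", "FC4", "C4", "Pz", "Oz"),
                          roi_channels = c("F3", "Fz", "FC3", "C3", "Cz"),
                          target_radius_mm = 80,
                          n_targets = 8L,
                          stai_params = list(
                            state = list(anxiety = c(34.7, 7.9),
                                         control = c(20.5, 8.3)),
                            trait = list(anxiety = c(44.2, 10.9),
                                         control = c(28.2, 11.4))),
                          demo_params = list(
                            age = list(anxiety = c(22.3, 2.5),
                                       control = c(21.4, 1.6)),
                            ehi = list(anxiety = c(93.1, 7.5),
                                       control = c(94.6, 6.8))),
                          tlx_params = list(mean = 8, sd = 3.5,
                                            adaptation_shift = 2.25,
                                            subject_sd = 2)) {
  cfg <- list(
    n_anxiety = as.integer(n_anxiety), n_control = as.integer(n_control),
    seed = as.integer(seed), rotation_deg = rotation_deg,
    n_trials_per_condition = n_trials_per_condition,
    learning_rate = learning_rate, retention_factor = retention_factor,
    motor_noise_sd = motor_noise_sd, motor_bias_sd = motor_bias_sd,
    rt_params = rt_params,
    velocity_params = velocity_params, mrp_params = mrp_params,
    noise_params = noise_params, artifact_rate = artifact_rate,
    artifact_amp = artifact_amp, sample_rate = sample_rate,
    epoch_window = epoch_window, channels = channels,
    roi_channels = roi_channels, target_radius_mm = target_radius_mm,
    n_targets = as.integer(n_targets), stai_params = stai_params,
    demo_params = demo_params, tlx_params = tlx_params)
  class(cfg) <- "cohort_config"
  validate_cohort_config(cfg)
}

#' @export
print.cohort_config <- function(x, ...) {
  cat("<cohort_config>\n")
  cat(sprintf("  groups: %d anxiety / %d control (seed %d)\n",
              x$n_anxiety, x$n_control, x$seed))
  cat(sprintf("  rotation: %g deg CCW; targets: %d @ %g mm\n",
              x$rotation_deg, x$n_targets, x$target_radius_mm))
  cat(sprintf("  trials: %s (total %d)\n",
              paste(names(x$n_trials_per_condition),
                    x$n_trials_per_condition, sep = "=", collapse = ", "),
              sum(x$n_trials_per_condition)))
  cat(sprintf("  learner: B=%g, retention=%g, motor noise %g deg\n",
              x$learning_rate, x$retention_factor, x$motor_noise_sd))
  cat(sprintf("  MRP template (uV): RP %g, NS %g, MP %g; deltas %g/%g/%g\n",
              x$mrp_params$rp, x$mrp_params$ns, x$mrp_params$mp,
              x$mrp_params$rp_delta, x$mrp_params$ns_delta,
              x$mrp_params$mp_delta))
  invisible(x)
}

task_conditions <- function() c("baseline", "adaptation", "retention", "washout")

validate_cohort_config <- function(cfg) {
  stop_cfg <- function(msg) stop("invalid cohort_config: ", msg, call. = FALSE)
  if (cfg$n_anxiety < 1L || cfg$n_control < 1L)
    stop_cfg("group sizes must be positive")
  tc <- cfg$n_trials_per_condition
  if (!all(task_conditions() %in% names(tc)))
    stop_cfg(paste("n_trials_per_condition must name",
                   paste(task_conditions(), collapse = ", ")))
  if (any(tc <= 0)) stop_cfg("all trial counts must be > 0")
  if (!(cfg$learning_rate > 0 && cfg$learning_rate < 1))
    stop_cfg("learning_rate must lie in (0, 1)")
  if (!(cfg$retention_factor > 0 && cfg$retention_factor <= 1))
    stop_cfg("retention_factor must lie in (0, 1]")
  if (cfg$motor_noise_sd < 0) stop_cfg("motor_noise_sd must be >= 0")
  if (cfg$motor_bias_sd < 0) stop_cfg("motor_bias_sd must be >= 0")
  if (cfg$artifact_rate < 0 || cfg$artifact_rate > 1)
    stop_cfg("artifact_rate must lie in [0, 1]")
  if (cfg$sample_rate <= 0) stop_cfg("sample_rate must be > 0")
  if (length(cfg$epoch_window) != 2L ||
      cfg$epoch_window[1] >= cfg$epoch_window[2])
    stop_cfg("epoch_window must be an increasing ms pair")
  if (!all(cfg$roi_channels %in% cfg$channels))
    stop_cfg("roi_channels must be a subset of channels")
  if (anyDuplicated(cfg$channels)) stop_cfg("channel names must be unique")
  cfg
}

#' Zero-noise variant of a cohort configuration
#'
#' Returns the same design with every stochastic term silenced: motor noise,
#' onset-latency and peak-speed spread, EEG broadband and 1/f noise, artifacts,
#' between-subject spread, questionnaire spread. Under this configuration the
#' full pipeline must recover the generator parameters exactly, which the test
#' suite uses as an end-to-end identity check.
#'
#' @param ... arguments forwarded to [cohort_config()].
#' @return a `cohort_config`.
#' @export
zero_noise_config <- function(...) {
  cfg <- cohort_config(...)
  cfg$motor_noise_sd <- 0
  cfg$motor_bias_sd <- 0
  cfg$rt_params$sdlog <- 0
  cfg$rt_params$subject_sd <- 0
  cfg$velocity_params$sd <- 0
  cfg$velocity_params$subject_sd <- 0
  cfg$mrp_params$subject_sd <- 0
  cfg$noise_params$broadband_sd <- 0
  cfg$noise_params$pink_sd <- 0
  cfg$artifact_rate <- 0
  cfg$tlx_params$sd <- 0
  cfg$tlx_params$subject_sd <- 0
  for (sc in names(cfg$stai_params))
    for (g in names(cfg$stai_params[[sc]]))
      cfg$stai_params[[sc]][[g]][2] <- 0
  for (v in names(cfg$demo_params))
    for (g in names(cfg$demo_params[[v]]))
      cfg$demo_params[[v]][[g]][2] <- 0
  cfg
}

#' Read / write a cohort configuration as YAML
#'
#' `write_config()` serializes a config; `read_config()` parses one, rejecting
#' unknown keys so that a typo in a pipeline config fails loudly rather than
#' silently falling back to a default.
#'
#' @param config a `cohort_config`.
#' @param path file path.
#' @return `read_config()` returns a validated `cohort_config`.
#' @export
write_config <- function(config, path) {
  x <- unclass(config)
  x$n_trials_per_condition <- as.list(x$n_trials_per_condition)
  yaml::write_yaml(x, path)
  invisible(path)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  known <- names(formals(cohort_config))
  bad <- setdiff(names(x), known)
  if (length(bad))
    stop("unknown config keys: ", paste(bad, collapse = ", "), call. = FALSE)
  if (!is.null(x$n_trials_per_condition))
    x$n_trials_per_condition <- unlist(x$n_trials_per_condition)
  for (nm in c("stai_params", "demo_params"))
    if (!is.null(x[[nm]]))
      x[[nm]] <- lapply(x[[nm]], function(v) lapply(v, unlist))
  do.call(cohort_config, x)
}

# wrap degrees into (-180, 180]
wrap_angle <- function(x) x - 360 * ceiling((x - 180) / 360)
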