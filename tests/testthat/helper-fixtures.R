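# Shared fixtures, built in code at test time.

# small, fast configs
tiny_counts <- c(baseline = 8, adaptation = 16, retention = 16, washout = 8)
small_counts <- c(baseline = 16, adaptation = 32, retention = 32, washout = 16)

tiny_zero_cfg <- function(seed = 1, ...) {
  suppressWarnings(zero_noise_config(
    seed = seed, n_anxiety = 2, n_control = 3,
    n_trials_per_condition = small_counts, ...))
}

# hand-built straight-line trajectory: constant speed v mm/s along `angle`
line_trajectory <- function(angle_deg = 0, v = 400, dt = 0.004, t_max = 0.4,
                            hold = 0) {
  t <- seq(0, t_max, by = dt)
  s <- pmax(t - hold, 0) * v
  structure(list(t = t, x = s * cospi(angle_deg / 180),
                 y = s * sinpi(angle_deg / 180),
                 cue_time = 0, target_deg = angle_deg, condition = "baseline",
                 trial_index = 1L, timeout_flag = FALSE),
            class = "trajectory")
}

rotate_traj <- function(traj, by_deg) {
  r <- by_deg * pi / 180
  out <- traj
  out$x <- traj$x * cos(r) - traj$y * sin(r)
  out$y <- traj$x * sin(r) + traj$y * cos(r)
  out$target_deg <- traj$target_deg + by_deg
  out
}

# epoch set with a single known waveform on every channel
waveform_epochs <- function(wave, n_trials = 4, channels = c("F3", "Fz", "FC3", "C3", "Cz"),
                            times = seq(-2000, 500, by = 4), sample_rate = 250) {
  stopifnot(length(wave) == length(times))
  arr <- array(rep(wave, each = n_trials * length(channels)),
               dim = c(n_trials, length(channels), length(times)))
  epoch_set(arr, times, channels, sample_rate,
            condition = "adaptation", participant = "S01")
}
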