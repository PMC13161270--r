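#' Component analysis windows
#'
#' The three movement-readiness-potential windows, in ms relative to movement
#' onset: readiness potential (RP) -1500 to -500, negative slope (NS) -500 to
#' -100, motor potential (MP) -100 to +100. Shared window boundaries are
#' closed-open toward the later window; only the final (MP) upper bound is
#' inclusive.
#'
#' @return named list of ms pairs.
#' @export
component_windows <- function() {
  list(rp = c(-1500, -500), ns = c(-500, -100), mp = c(-100, 100))
}

# boundary ownership: lower bound inclusive; upper bound inclusive only when
# requested (used for the last analysis window)
window_mask <- function(times, win, close_upper = FALSE) {
  if (close_upper) times >= win[1] & times <= win[2]
  else times >= win[1] & times < win[2]
}

#' 1/f ("pink") noise via spectral shaping
#'
#' White Gaussian noise is shaped in the frequency domain with a 1/sqrt(f)
#' amplitude envelope (zero DC) and rescaled analytically so each series has
#' the requested per-sample standard deviation in expectation.
#'
#' @param n samples per series.
#' @param m number of independent series.
#' @param sd target per-sample SD.
#' @return numeric `n` x `m` matrix.
#' @export
pink_noise <- function(n, m = 1L, sd = 1) {
  if (sd == 0) return(matrix(0, n, m))
  # pad to a 5-smooth length: FFTs of awkward (near-prime) lengths are slow
  n2 <- stats::nextn(n, c(2, 3, 5))
  white <- matrix(stats::rnorm(n2 * m), n2, m)
  k <- seq_len(n2) - 1L
  f <- pmin(k, n2 - k)
  filt <- ifelse(f == 0, 0, 1 / sqrt(pmax(f, 1)))
  y <- Re(stats::mvfft(stats::mvfft(white) * filt, inverse = TRUE)) / n2
  y <- y[seq_len(n), , drop = FALSE]      # stationary: truncation keeps the SD
  y * sd / sqrt(mean(filt^2))
}

#' Movement-readiness-potential waveform template
#'
#' Piecewise template on the epoch time axis: flat zero before -1500 ms, a
#' linear ramp 0 -> `rp` over [-1500, -500) ms, a steeper ramp `rp` -> `ns`
#' over [-500, -100) ms, a Gaussian excursion reaching `mp` at 0 ms over
#' [-100, +100] ms, then a linear relaxation back to zero by +500 ms.
#' The anxiety group's attenuation deltas (and the stage / condition shifts)
#' are applied as constant positive offsets *within* the NS and MP analysis
#' windows, using exactly the window masks that [component_means()] averages
#' over, so configured group differences propagate through the pipeline
#' without discretization error.
#'
#' @param times epoch time axis in ms.
#' @param config a [cohort_config()].
#' @param group `"anxiety"` or `"control"`.
#' @param condition `"adaptation"` or `"retention"`.
#' @param stage `"early"` or `"late"`.
#' @param subject_shift participant-level amplitude offset (microvolts),
#'   applied uniformly from -1500 ms onward (outside the baseline window, so
#'   it survives baseline correction as a subject random intercept).
#' @return numeric vector of template amplitudes (microvolts).
#' @export
mrp_template <- function(times, config, group, condition, stage,
                         subject_shift = 0) {
  group <- match.arg(group, c("anxiety", "control"))
  condition <- match.arg(condition, c("adaptation", "retention"))
  stage <- match.arg(stage, c("early", "late"))
  mp_par <- config$mrp_params
  w <- component_windows()
  v <- numeric(length(times))

  i1 <- window_mask(times, w$rp)
  v[i1] <- mp_par$rp * (times[i1] + 1500) / 1000
  i2 <- window_mask(times, w$ns)
  v[i2] <- mp_par$rp + (mp_par$ns - mp_par$rp) * (times[i2] + 500) / 400
  sigma <- 40
  i3 <- window_mask(times, w$mp, close_upper = TRUE)
  v[i3] <- mp_par$ns + (mp_par$mp - mp_par$ns) * exp(-times[i3]^2 / (2 * sigma^2))
  v_end <- mp_par$ns + (mp_par$mp - mp_par$ns) * exp(-100^2 / (2 * sigma^2))
  i4 <- times > 100
  v[i4] <- v_end * pmax(1 - (times[i4] - 100) / 400, 0)

  ns_mask <- window_mask(times, w$ns)
  mp_mask <- window_mask(times, w$mp, close_upper = TRUE)
  rp_mask <- window_mask(times, w$rp)
  if (group == "anxiety") {
    v[rp_mask] <- v[rp_mask] + mp_par$rp_delta
    v[ns_mask] <- v[ns_mask] + mp_par$ns_delta
    v[mp_mask] <- v[mp_mask] + mp_par$mp_delta
  }
  if (stage == "early") v[ns_mask] <- v[ns_mask] + mp_par$ns_early_shift
  if (condition == "retention") v[mp_mask] <- v[mp_mask] + mp_par$mp_retention_shift
  v[times >= -1500] <- v[times >= -1500] + subject_shift
  v
}

#' Simulate movement-locked epochs for one participant and condition
#'
#' Region-of-interest channels carry the MRP template for the trial's stage
#' (early = first half of the condition's trials, matching the downstream
#' median split); all channels receive additive broadband white and 1/f noise.
#' A fraction `artifact_rate` of trials receives a large-amplitude 100 ms
#' transient on every channel to exercise rejection bookkeeping.
#'
#' @inheritParams mrp_template
#' @param n_trials number of trials (epochs) to simulate.
#' @return an [epoch_set()].
#' @export
simulate_epochs <- function(config, group, condition, n_trials,
                            subject_shift = 0) {
  sr <- config$sample_rate
  times <- seq(config$epoch_window[1], config$epoch_window[2], by = 1000 / sr)
  n_s <- length(times)
  n_c <- length(config$channels)
  n_t <- as.integer(n_trials)

  np <- config$noise_params
  if (np$broadband_sd > 0) {
    data <- array(stats::rnorm(n_t * n_c * n_s, 0, np$broadband_sd),
                  dim = c(n_t, n_c, n_s))
  } else data <- array(0, dim = c(n_t, n_c, n_s))
  if (np$pink_sd > 0) {
    p <- pink_noise(n_s, n_t * n_c, np$pink_sd)
    data <- data + array(t(p), dim = c(n_t, n_c, n_s))
  }

  tmpl <- list(
    early = mrp_template(times, config, group, condition, "early", subject_shift),
    late = mrp_template(times, config, group, condition, "late", subject_shift))
  n_early <- ceiling(n_t / 2)
  stage <- rep(c("early", "late"), c(n_early, n_t - n_early))
  roi_idx <- match(config$roi_channels, config$channels)
  for (st in c("early", "late")) {
    idx <- which(stage == st)
    if (!length(idx)) next
    add <- rep(tmpl[[st]], each = length(idx))
    for (ci in roi_idx)
      data[idx, ci, ] <- data[idx, ci, ] + add
  }

  if (config$artifact_rate > 0) {
    hit <- which(stats::runif(n_t) < config$artifact_rate)
    blink_len <- max(3L, round(0.1 * sr))
    blink <- config$artifact_amp *
      (0.5 - 0.5 * cos(2 * pi * seq_len(blink_len) / (blink_len + 1)))
    for (tr in hit) {
      at <- sample.int(n_s - blink_len, 1L)
      span <- at:(at + blink_len - 1L)
      data[tr, , span] <- data[tr, , span] +
        rep(blink, each = n_c)
    }
  }

  epoch_set(data, times = times, channels = config$channels,
            sample_rate = sr, condition = condition)
}
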